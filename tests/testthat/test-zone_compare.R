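test_that("zone areas are cell counts times cell area", {
  z <- toy_zone_map(rep(1L, 100), 10, 10)  # 800 m cells: 0.64 km2 each
  a <- zone_areas(z)
  expect_equal(a$area_km2, 64)
  # 60/40 split of a 10x10 grid
  z2 <- toy_zone_map(c(rep(1L, 60), rep(2L, 40)), 10, 10)
  a2 <- zone_areas(z2)
  expect_equal(a2$area_km2, c(38.4, 25.6))
  expect_equal(sum(a2$area_km2), nrow(z2) * cell_area_km2(z2))
  # an absent zone id simply has no row (area 0)
  expect_false(3L %in% a2$zone)
})

test_that("overlap rates reproduce hand-counted cell arithmetic", {
  # reference zone covers 40 cells; the GF zone covers 30 of them
  ref <- toy_zone_map(c(rep(1L, 40), rep(2L, 60)), 10, 10)
  gf <- toy_zone_map(c(rep(1L, 30), rep(2L, 70)), 10, 10)
  rep1 <- overlap_report(gf, ref, zone_correspondence("1", "1"))
  expect_equal(rep1$rate, 75)  # 30 of 40 reference cells
  expect_equal(rep1$overlap_km2, 30 * 0.64)
  # identical maps, identity correspondence: all rates 100
  rep2 <- overlap_report(ref, ref)
  expect_equal(rep2$rate, c(100, 100))
  expect_equal(average_overlap_rate(rep2), 100)
  # label-disjoint maps: all rates 0
  swapped <- toy_zone_map(c(rep(2L, 40), rep(1L, 60)), 10, 10)
  rep3 <- overlap_report(ref, swapped)
  expect_equal(rep3$rate, c(0, 0))
  # unknown ids in the correspondence are rejected
  expect_error(overlap_report(gf, ref, zone_correspondence("9", "1")),
               "unknown zone")
})

test_that("denominator conventions and averaging options are consistent", {
  ref <- toy_zone_map(c(rep(1L, 40), rep(2L, 60)), 10, 10)
  gf <- toy_zone_map(c(rep(1L, 50), rep(2L, 50)), 10, 10)
  co <- zone_correspondence(c("1", "2"), c("1", "2"))
  r_ref <- overlap_report(gf, ref, co, denominator = "reference")
  r_gf <- overlap_report(gf, ref, co, denominator = "gf")
  r_un <- overlap_report(gf, ref, co, denominator = "union")
  # pair 1: overlap 40 cells; ref 40, gf 50, union 50
  expect_equal(r_ref$rate[1], 100)
  expect_equal(r_gf$rate[1], 80)
  expect_equal(r_un$rate[1], 80)
  # area-weighted vs simple average
  expect_equal(average_overlap_rate(r_ref),
               sum(r_ref$rate * r_ref$denominator_km2) /
                 sum(r_ref$denominator_km2))
  r_simple <- overlap_report(gf, ref, co, average = "simple")
  expect_equal(average_overlap_rate(r_simple), mean(r_ref$rate))
})

test_that("many-to-one correspondences compare label sets", {
  ref <- toy_zone_map(rep(1:4, each = 25), 10, 10)
  gf <- toy_zone_map(rep(c(1L, 2L), each = 50), 10, 10)
  co <- zone_correspondence(c("1", "2"), c("1,2", "3,4"))
  rep <- overlap_report(gf, ref, co)
  expect_equal(rep$rate, c(100, 100))
  expect_equal(rep$ref_zones, c("1,2", "3,4"))
})

test_that("overlap areas are symmetric and partition the shared mask", {
  set.seed(71)
  za <- toy_zone_map(sample(1:3, 144, replace = TRUE), 12, 12)
  zb <- toy_zone_map(sample(1:2, 144, replace = TRUE), 12, 12)
  ab <- overlap_report(za, zb, zone_correspondence("2", "1"))
  ba <- overlap_report(zb, za, zone_correspondence("1", "2"))
  expect_equal(ab$overlap_km2, ba$overlap_km2)
  # over the full product partition, overlaps sum to the shared area
  co_full <- zone_correspondence(
    as.character(rep(1:3, each = 2)), as.character(rep(1:2, times = 3)))
  full <- overlap_report(za, zb, co_full)
  expect_equal(sum(full$overlap_km2), 144 * 0.64)
})

test_that("rates are invariant to uniform raster refinement", {
  set.seed(72)
  base_z <- sample(1:3, 25, replace = TRUE)
  base_r <- sample(1:2, 25, replace = TRUE)
  refine <- function(z, n) {
    m <- matrix(z, n, n)
    fine <- m[rep(seq_len(n), each = 2), rep(seq_len(n), each = 2)]
    toy_zone_map(as.vector(fine), 2 * n, 2 * n, cellsize = 400)
  }
  co <- zone_correspondence(c("1", "2"), c("1", "2"))
  coarse <- overlap_report(toy_zone_map(base_z, 5, 5),
                           toy_zone_map(base_r, 5, 5), co)
  fine <- overlap_report(refine(base_z, 5), refine(base_r, 5), co)
  expect_equal(fine$rate, coarse$rate)
})

test_that("reports regenerate identically from persisted zone maps", {
  set.seed(73)
  gf <- toy_zone_map(sample(1:4, 100, replace = TRUE), 10, 10)
  ref <- toy_zone_map(sample(1:4, 100, replace = TRUE), 10, 10)
  rep1 <- overlap_report(gf, ref)
  dir <- withr::local_tempdir()
  write_zone_map(gf, file.path(dir, "gf.asc"))
  write_zone_map(ref, file.path(dir, "ref.asc"))
  rep2 <- overlap_report(read_zone_map(file.path(dir, "gf.asc")),
                         read_zone_map(file.path(dir, "ref.asc")))
  expect_identical(as.data.frame(rep1), as.data.frame(rep2))
  expect_identical(average_overlap_rate(rep1), average_overlap_rate(rep2))
})

test_that("backward delineation forces the reference zone count", {
  blobs <- six_blobs(n_per = 50)
  n <- nrow(blobs$points)
  grid <- climate_grid(tibble::tibble(x = (seq_len(n) - 0.5) * 800, y = 400))
  scan <- cluster_scan(blobs$points, k_range = 2:9, seed = 6)
  z4 <- backward_delineate(scan, grid, 4)
  z9 <- backward_delineate(scan, grid, 9)
  expect_equal(sort(unique(z4$zone)), 1:4)
  expect_equal(sort(unique(z9$zone)), 1:9)
  # forcing the forward-selected k reproduces the forward map
  sel <- select_k(scan)
  fwd <- make_zone_map(scan, grid, sel$k)
  expect_identical(as.data.frame(backward_delineate(scan, grid, sel$k)),
                   as.data.frame(fwd))
  # the k = 6 partition refines k = 4: cells of one fine zone rarely straddle
  z6 <- make_zone_map(scan, grid, 6)
  frac_consistent <- mean(vapply(seq_len(n), function(i) {
    peers <- z6$zone == z6$zone[i]
    names(which.max(table(z4$zone[peers]))) == as.character(z4$zone[i])
  }, TRUE))
  expect_gte(frac_consistent, 0.9)
})
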