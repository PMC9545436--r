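#' Per-zone areas in square kilometres
#'
#' Equal-area cell counting: `area(zone) = cell count x cell area`. Requires
#' the zone map's grid to be in a projected/equal-area system (cell size in
#' metres).
#'
#' @param z A [zone_map()].
#' @return Tibble with `zone`, `n_cells`, `area_km2`; areas sum to the total
#'   masked-range area.
#' @export
zone_areas <- function(z) {
  stopifnot(inherits(z, "zone_map"))
  ca <- cell_area_km2(z)
  if (is.null(ca) || !is.finite(ca)) stop("cell area is not set", call. = FALSE)
  dplyr::count(tibble::as_tibble(z), .data$zone, name = "n_cells") |>
    dplyr::mutate(area_km2 = .data$n_cells * ca) |>
    dplyr::arrange(.data$zone)
}

#' Zone correspondence table
#'
#' Declares which sets of zones are compared between a gradient-forest map
#' and a reference map. Many-to-one pairings are supported: give zone ids as
#' comma-separated strings or integer vectors (e.g. gf `"2,4"` vs four
#' reference zones `"1,2,4,5"`).
#'
#' @param gf_zones,ref_zones Vectors (character `"2,4"` or list of integer
#'   vectors) of equal length defining the pairs.
#' @return Tibble with `pair`, `gf_zones`, `ref_zones` (list-columns of
#'   integer vectors).
#' @export
zone_correspondence <- function(gf_zones, ref_zones) {
  parse_ids <- function(x) {
    if (is.list(x)) return(lapply(x, as.integer))
    lapply(strsplit(as.character(x), "[,;+ ]+"), as.integer)
  }
  gf <- parse_ids(gf_zones)
  rf <- parse_ids(ref_zones)
  if (length(gf) != length(rf)) {
    stop("gf_zones and ref_zones must pair up", call. = FALSE)
  }
  tibble::tibble(pair = seq_along(gf), gf_zones = gf, ref_zones = rf)
}

#' Overlap report between two zone maps
#'
#' Co-registers the two maps on their shared cells and, for each
#' correspondence pair, counts the cells whose labels fall in the pair's GF
#' set and reference set simultaneously. The overlap rate is
#' `100 * overlap area / denominator area`; the averaged rate is the
#' area-weighted mean over pairs (weights = denominator areas), with a
#' simple-mean option since reference delineation practice varies.
#'
#' @param a The gradient-forest [zone_map()].
#' @param b The reference [zone_map()].
#' @param correspondence A [zone_correspondence()] tibble covering the zone
#'   ids being compared (default: identity over the shared zone ids).
#' @param denominator Rate denominator: `"reference"` (default; the
#'   common-garden zone area), `"gf"`, or `"union"`.
#' @param average `"area_weighted"` (default) or `"simple"`.
#' @return An `overlap_report`: tibble of per-pair rows (overlap area km2,
#'   denominator area, rate %) with attributes `average_rate`,
#'   `denominator`, `total_area_a/b` (km2).
#' @export
overlap_report <- function(a, b, correspondence = NULL,
                           denominator = c("reference", "gf", "union"),
                           average = c("area_weighted", "simple")) {
  stopifnot(inherits(a, "zone_map"), inherits(b, "zone_map"))
  denominator <- match.arg(denominator)
  average <- match.arg(average)
  if (grid_cellsize(a) != grid_cellsize(b)) {
    stop("zone maps are on different grids; resample first", call. = FALSE)
  }
  ca <- cell_area_km2(a)
  joined <- dplyr::inner_join(
    stats::setNames(tibble::as_tibble(a), c("x", "y", "zone_a")),
    stats::setNames(tibble::as_tibble(b), c("x", "y", "zone_b")),
    by = c("x", "y"))
  if (is.null(correspondence)) {
    shared <- sort(intersect(unique(a$zone), unique(b$zone)))
    correspondence <- zone_correspondence(as.list(shared), as.list(shared))
  }
  known_a <- unique(a$zone); known_b <- unique(b$zone)
  bad <- c(setdiff(unlist(correspondence$gf_zones), known_a),
           setdiff(unlist(correspondence$ref_zones), known_b))
  if (length(bad) > 0) {
    stop(sprintf("correspondence references unknown zone id(s): %s",
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  }
  rows <- purrr::pmap_dfr(correspondence, function(pair, gf_zones, ref_zones) {
    in_a <- joined$zone_a %in% gf_zones
    in_b <- joined$zone_b %in% ref_zones
    ov <- sum(in_a & in_b) * ca
    area_gf <- sum(a$zone %in% gf_zones) * ca
    area_ref <- sum(b$zone %in% ref_zones) * ca
    den <- switch(denominator, reference = area_ref, gf = area_gf,
                  union = area_gf + area_ref - ov)
    tibble::tibble(
      pair = pair,
      gf_zones = paste(gf_zones, collapse = ","),
      ref_zones = paste(ref_zones, collapse = ","),
      overlap_km2 = ov, gf_area_km2 = area_gf, ref_area_km2 = area_ref,
      denominator_km2 = den,
      rate = if (den > 0) 100 * ov / den else NA_real_,
      empty_denominator = den <= 0)
  })
  w <- rows$denominator_km2
  ok <- !rows$empty_denominator
  avg <- if (average == "area_weighted") {
    sum(rows$rate[ok] * w[ok]) / sum(w[ok])
  } else mean(rows$rate[ok])
  structure(rows,
            class = c("overlap_report", class(tibble::tibble())),
            average_rate = avg, denominator = denominator, average = average,
            total_area_a = nrow(a) * ca, total_area_b = nrow(b) * ca)
}

#' Averaged overlap rate of a report
#' @param report An `overlap_report`.
#' @return The averaged overlap rate (%).
#' @export
average_overlap_rate <- function(report) attr(report, "average_rate")

#' Re-delineate at a forced number of zones (backward comparison)
#'
#' Bypasses [select_k()] and cuts the scanned clustering at the k of an
#' existing reference delineation, so the GF surface can be compared
#' backward against it.
#'
#' @param scan A `cluster_scan`.
#' @param grid The `genomic_grid` the scan points came from.
#' @param k Zone count matching the reference map (must be in the scan range).
#' @return A [zone_map()] with exactly `k` labels.
#' @export
backward_delineate <- function(scan, grid, k) {
  make_zone_map(scan, grid, k)
}
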