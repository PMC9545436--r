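small_fitted_model <- function(seed = 51) {
  climate <- iid_climate(250, seed = seed)
  set.seed(seed)
  drivers <- rep(c("MCMT", "EMT", "MAP", "Eref"), 3)
  dos <- sapply(drivers, function(v) {
    stats::rbinom(250, 2, stats::plogis(2.5 * scale(climate[[v]])[, 1]))
  })
  colnames(dos) <- sprintf("snp_%02d", seq_along(drivers))
  model <- fit_gradient_forest(genotype_matrix(dos,
                                               sample_ids = climate$sample_id),
                               climate, n_trees = 60, seed = seed)
  list(model = model, climate = climate)
}

test_that("grid transformation clamps to the training envelope", {
  mm <- small_fitted_model()
  model <- mm$model
  lo <- model$ranges["lo", ]
  hi <- model$ranges["hi", ]
  cells <- tibble::as_tibble(lapply(
    stats::setNames(climate_variable_names(), climate_variable_names()),
    function(v) c(lo[[v]] - 1, hi[[v]] + 1)))
  cells <- dplyr::bind_cols(tibble::tibble(x = c(400, 1200), y = c(400, 400)),
                            cells)
  grid <- climate_grid(cells)
  gg <- transform_grid(model, grid)
  totals <- vapply(model$turnover, `[[`, numeric(1), "total")
  for (v in names(model$turnover)) {
    expect_equal(gg[[v]][1], 0)           # below training minimum
    expect_equal(gg[[v]][2], totals[[v]]) # beyond training maximum
  }
  # a missing band is named
  expect_error(transform_grid(model, climate_grid(cells[c("x", "y", "MAT")])),
               "MWMT")
})

test_that("transformation is bandwise monotone along a monotone climate axis", {
  mm <- small_fitted_model()
  model <- mm$model
  lo <- model$ranges["lo", ]
  hi <- model$ranges["hi", ]
  n <- 50
  cells <- tibble::as_tibble(lapply(
    stats::setNames(climate_variable_names(), climate_variable_names()),
    function(v) seq(lo[v], hi[v], length.out = n)))
  cells$x <- (seq_len(n) - 0.5) * 800
  cells$y <- 400
  gg <- transform_grid(model, climate_grid(cells))
  for (v in climate_variable_names()) {
    expect_true(all(diff(gg[[v]]) >= -1e-12))
  }
})

test_that("table and grid transformation paths agree on the training samples", {
  mm <- small_fitted_model()
  ct <- transform_climate(mm$model, mm$climate)
  cells <- mm$climate
  cells$x <- (seq_len(nrow(cells)) - 0.5) * 800
  cells$y <- 400
  gg <- transform_grid(mm$model, climate_grid(cells[c("x", "y",
                                                      climate_variable_names())]))
  for (v in climate_variable_names()) {
    expect_equal(gg[[v]], ct[[v]], tolerance = 1e-12)
    # direct turnover evaluation is the definition of both paths
    expect_equal(ct[[v]], predict(mm$model$turnover[[v]], mm$climate[[v]]),
                 tolerance = 1e-12)
  }
})

# cells-by-bands tibble with an exact target sample covariance
grid_with_covariance <- function(Sigma, n = 200, seed = 3) {
  set.seed(seed)
  p <- ncol(Sigma)
  X <- matrix(stats::rnorm(n * p), n, p)
  X <- scale(X, center = TRUE, scale = FALSE)
  # whiten the realized covariance, then color with the target
  X <- X %*% solve(chol(stats::cov(X)))
  X <- X %*% chol(Sigma)
  out <- tibble::as_tibble(as.data.frame(X))
  names(out) <- sprintf("band%d", seq_len(p))
  out$x <- seq_len(n) * 800 - 400
  out$y <- 400
  climate_grid(out[c("x", "y", sprintf("band%d", seq_len(p)))])
}

test_that("PCA reproduces closed-form variance fractions for a 2x2 covariance", {
  gg <- grid_with_covariance(matrix(c(2, 1, 1, 2), 2))
  out <- pca_scores(gg, n_components = 2)
  # eigenvalues of [[2,1],[1,2]] are 3 and 1
  expect_equal(pca_variance_fractions(out), c(0.75, 0.25), tolerance = 1e-9)
})

test_that("PCA fractions, reconstruction and sign convention behave", {
  gg <- grid_with_covariance(diag(c(4, 2, 1)) + 0.5, n = 120, seed = 5)
  out <- pca_scores(gg, n_components = 3)
  vf <- pca_variance_fractions(out)
  expect_true(all(diff(vf) <= 1e-12))
  expect_equal(sum(vf), 1, tolerance = 1e-9)
  # full-rank reconstruction of the centered band matrix
  L <- pca_loadings(out)
  S <- as.matrix(out[sprintf("PC%d", 1:3)])
  M <- as.matrix(gg[grid_bands(gg)])
  Mc <- scale(M, center = TRUE, scale = FALSE)
  expect_equal(S %*% t(L), unclass(Mc), tolerance = 1e-8,
               ignore_attr = TRUE)
  # largest-magnitude loading of each component is positive
  for (j in 1:3) {
    expect_gte(L[which.max(abs(L[, j])), j], 0)
  }
  # a rank-1 grid loads everything on PC1
  gg1 <- gg
  gg1$band2 <- gg1$band1 * 2
  gg1$band3 <- gg1$band1 * -1
  out1 <- pca_scores(gg1, n_components = 1)
  expect_equal(pca_variance_fractions(out1)[1], 1, tolerance = 1e-9)
  # all-constant bands are an error
  ggc <- gg
  for (b in grid_bands(ggc)) ggc[[b]] <- 1
  expect_error(pca_scores(ggc), "constant")
})

test_that("RGB mapping is a recorded, reproducible linear stretch", {
  gg <- grid_with_covariance(diag(3), n = 150, seed = 7)
  out <- pca_scores(gg, n_components = 3)
  rgb_mm <- rgb_map(out, stretch = "minmax")
  expect_equal(rgb_mm$red[which.min(out$PC1)], 0L)
  expect_equal(rgb_mm$red[which.max(out$PC1)], 255L)
  # identical scores give identical colors
  out2 <- out[c(1, 1, 2), ]
  rgb2 <- rgb_map(out2, stretch = "minmax")
  expect_identical(rgb2$hex[1], rgb2$hex[2])
  # constant band maps to mid-gray with a warning
  outc <- out
  outc$PC3 <- 0
  expect_warning(rgbc <- rgb_map(outc, stretch = "minmax"), "mid-gray")
  expect_true(all(rgbc$blue == 128L))
})

test_that("a two-regime surface yields a bimodal color distribution", {
  set.seed(9)
  n <- 400
  regime <- rep(c(0, 8), each = n / 2)
  gg <- tibble::tibble(x = seq_len(n) * 800 - 400, y = 400,
                       PC1 = regime + stats::rnorm(n, sd = 0.4),
                       PC2 = -regime + stats::rnorm(n, sd = 0.4),
                       PC3 = stats::rnorm(n, sd = 0.4))
  cols <- rgb_map(climate_grid(gg), stretch = "percentile")
  # red channel splits into a low and a high mode with an empty middle
  expect_gt(mean(cols$red < 64), 0.4)
  expect_gt(mean(cols$red > 191), 0.4)
  expect_lt(mean(cols$red >= 64 & cols$red <= 191), 0.1)
})
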