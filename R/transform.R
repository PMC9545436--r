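#' Transform a climate grid into genomic-composition space
#'
#' Evaluates every predictor's aggregate turnover function at each masked-in
#' cell's climate, producing the multidimensional genomic-composition surface:
#' cells with similar transformed vectors are expected to host similarly
#' adapted genotypes. Values are linearly interpolated between turnover
#' breakpoints, clamped to 0 below the training range and to the predictor's
#' total importance above it.
#'
#' @param model A `gf_model`.
#' @param grid A [climate_grid()] carrying all model predictors as bands.
#' @param rule Breakpoint interpolation: `"linear"` (default) or
#'   `"staircase"` (exact step evaluation, used by oracle tests).
#' @return A `genomic_grid` tibble: `x`, `y` plus one transformed band per
#'   predictor (units: cumulative importance). Attach PCA scores with
#'   [pca_scores()].
#' @export
transform_grid <- function(model, grid, rule = c("linear", "staircase")) {
  stopifnot(inherits(model, "gf_model"))
  rule <- match.arg(rule)
  preds <- names(model$turnover)
  missing <- setdiff(preds, names(grid))
  if (length(missing) > 0) {
    stop(sprintf("predictor %s missing from grid", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  out <- tibble::tibble(x = grid$x, y = grid$y)
  for (v in preds) {
    out[[v]] <- predict(model$turnover[[v]], grid[[v]], rule = rule)
  }
  out <- structure(out, class = c("genomic_grid", class(tibble::tibble())))
  set_grid_meta(out, cellsize = grid_cellsize(grid), crs = attr(grid, "crs"))
}

#' Transform a per-sample climate table
#'
#' Same evaluation as [transform_grid()] but on a sample table, so training
#' locations can be placed in the transformed space (e.g. for biplots).
#'
#' @inheritParams transform_grid
#' @param climate Climate tibble with the model predictors.
#' @return Tibble of transformed predictor columns (plus `sample_id` if
#'   present).
#' @export
transform_climate <- function(model, climate, rule = c("linear", "staircase")) {
  rule <- match.arg(rule)
  keep <- intersect(c("sample_id", "population_id"), names(climate))
  out <- tibble::as_tibble(climate[keep])
  for (v in names(model$turnover)) {
    out[[v]] <- predict(model$turnover[[v]], climate[[v]], rule = rule)
  }
  out
}

#' Principal components of the transformed genomic surface
#'
#' PCA on the centered (not variance-scaled) transformed bands over all
#' masked-in cells. Bands share the cumulative-importance scale, so skipping
#' variance scaling preserves the importance weighting that makes dominant
#' predictors dominate the map. Component signs follow a deterministic
#' convention: the largest-magnitude loading of each component is made
#' positive.
#'
#' @param gg A `genomic_grid` from [transform_grid()] (or any tibble of cells
#'   by numeric bands, with optional `x`/`y` columns).
#' @param n_components Number of score columns to attach (default 3, the
#'   components used for RGB maps and zonation).
#' @return The grid with `PC1..PCk` columns appended; attributes
#'   `variance_fractions` (all components) and `loadings` (bands x components
#'   matrix, biplot vectors).
#' @export
pca_scores <- function(gg, n_components = 3) {
  bands <- grid_bands(gg)
  bands <- setdiff(bands, grep("^PC[0-9]+$", names(gg), value = TRUE))
  M <- as.matrix(gg[bands])
  keep <- apply(M, 2, function(col) stats::var(col) > 0)
  if (!any(keep)) stop("all bands are constant; PCA undefined", call. = FALSE)
  if (nrow(M) < n_components) {
    stop("fewer masked-in cells than requested components", call. = FALSE)
  }
  Mc <- scale(M, center = TRUE, scale = FALSE)
  pc <- stats::prcomp(Mc, center = FALSE, scale. = FALSE)
  # deterministic sign: largest |loading| of each component positive
  for (j in seq_len(ncol(pc$rotation))) {
    k <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[k, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  n_components <- min(n_components, ncol(pc$x))
  out <- gg
  for (j in seq_len(n_components)) out[[paste0("PC", j)]] <- pc$x[, j]
  attr(out, "variance_fractions") <- varfrac
  attr(out, "loadings") <- pc$rotation
  attr(out, "pca_center") <- attr(Mc, "scaled:center")
  out
}

#' Variance fractions and loadings of an attached PCA
#' @param gg Output of [pca_scores()].
#' @return `pca_variance_fractions()`: numeric vector over all components;
#'   `pca_loadings()`: bands x components matrix.
#' @export
pca_variance_fractions <- function(gg) attr(gg, "variance_fractions")

#' @rdname pca_variance_fractions
#' @export
pca_loadings <- function(gg) attr(gg, "loadings")

#' Map the top three principal components to RGB channels
#'
#' Linearly rescales each of PC1-PC3 to 0..255 (PC1 = red, PC2 = green,
#' PC3 = blue) so that similar colors mean similar expected genomic
#' composition. The stretch parameters are recorded as attributes so colors
#' are reproducible.
#'
#' @param gg Output of [pca_scores()] with at least `PC1..PC3`.
#' @param stretch `"percentile"` (default; 2nd-98th percentile, clipped) or
#'   `"minmax"`.
#' @return Tibble `x`, `y`, `red`, `green`, `blue` (0-255) and `hex`; stretch
#'   bounds in `attr(, "stretch")`. Constant score bands map to mid-gray 128
#'   with a warning.
#' @export
rgb_map <- function(gg, stretch = c("percentile", "minmax")) {
  stretch <- match.arg(stretch)
  pcs <- c("PC1", "PC2", "PC3")
  if (!all(pcs %in% names(gg))) {
    stop("rgb_map needs PC1..PC3 score bands (run pca_scores first)",
         call. = FALSE)
  }
  bounds <- matrix(NA_real_, 2, 3, dimnames = list(c("lo", "hi"), pcs))
  chan <- lapply(pcs, function(v) {
    s <- gg[[v]]
    b <- if (stretch == "percentile") {
      stats::quantile(s, c(0.02, 0.98), names = FALSE)
    } else range(s)
    bounds[, v] <<- b
    if (b[2] <= b[1]) {
      warning(sprintf("constant score band %s mapped to mid-gray", v))
      return(rep(128L, length(s)))
    }
    as.integer(round(pmin(pmax((s - b[1]) / (b[2] - b[1]), 0), 1) * 255))
  })
  out <- tibble::tibble(x = gg$x, y = gg$y, red = chan[[1]],
                        green = chan[[2]], blue = chan[[3]])
  out$hex <- grDevices::rgb(out$red, out$green, out$blue, maxColorValue = 255)
  attr(out, "stretch") <- list(method = stretch, bounds = bounds)
  out
}
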