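#' Fit one SNP's regression forest against the climate predictors
#'
#' Grows `n_trees` CART regression trees on bootstrap samples, regressing the
#' individual-level 0/1/2 dosage on the climate variables, and records every
#' split as (predictor, split value, impurity reduction). The out-of-bag fit
#' is `oob_r2 = 1 - MSE_oob / Var(dosages)` (may be negative). Samples never
#' out-of-bag are excluded from `MSE_oob`; if fewer than half the samples have
#' an OOB prediction the fit is flagged and `oob_r2` set to 0 so degenerate
#' settings (e.g. `n_trees = 1`) cannot produce an undefined or spurious R^2.
#'
#' @param dosages Numeric vector of 0/1/2 dosages (NA allowed: the forest is
#'   fit on the SNP's complete cases).
#' @param climate Climate tibble with the 20 predictor columns (and optionally
#'   `sample_id`), one row per element of `dosages`.
#' @param n_trees Number of trees (default 200).
#' @param mtry Predictors tried per split (default `floor(p / 3)`).
#' @param min_node Minimum samples per child node (default 5).
#' @param seed Integer seed; the fit is deterministic given it.
#' @param n_bins Number of equal-width importance bins per predictor
#'   (default 101).
#' @param return_splits Keep the full split-event table (memory-heavy for
#'   large forests; needed for per-SNP turnover curves and oracle checks).
#' @param snp_id Identifier stored on the fit.
#' @param min_cases Minimum complete cases required (default 30).
#' @param ranges Optional named list/matrix of per-predictor `c(lo, hi)` bin
#'   ranges; defaults to the observed range of each predictor.
#' @return An object of class `snp_forest`: list with `snp_id`, `oob_r2`,
#'   `oob_fraction`, `flagged`, per-predictor `importance`, `bin_importance`
#'   (predictors x bins matrix), `bin_ranges`, `n_cases`, and `splits` (tibble)
#'   when requested.
#' @export
fit_snp_forest <- function(dosages, climate, n_trees = 200, mtry = NULL,
                           min_node = 5, seed = 1, n_bins = 101,
                           return_splits = FALSE, snp_id = "snp",
                           min_cases = 30, ranges = NULL) {
  X <- as.matrix(climate[intersect(climate_variable_names(), names(climate))])
  if (ncol(X) == 0) X <- as.matrix(climate[vapply(climate, is.numeric, TRUE)])
  if (nrow(X) != length(dosages)) {
    stop("dosages and climate rows are misaligned", call. = FALSE)
  }
  ok <- !is.na(dosages)
  X <- X[ok, , drop = FALSE]
  y <- as.numeric(dosages[ok])
  if (length(y) < min_cases) {
    stop(sprintf("%s: only %d complete cases (need >= %d)", snp_id, length(y),
                 min_cases), call. = FALSE)
  }
  if (stats::var(y) == 0) {
    stop(sprintf("%s: constant dosage vector, R^2 undefined", snp_id),
         call. = FALSE)
  }
  p <- ncol(X)
  if (is.null(mtry)) mtry <- max(1L, floor(p / 3))
  if (is.null(ranges)) {
    lo <- apply(X, 2, min)
    hi <- apply(X, 2, max)
  } else {
    rg <- do.call(cbind, as.list(as.data.frame(ranges)))
    lo <- rg[1, colnames(X)]
    hi <- rg[2, colnames(X)]
  }
  fit <- .fit_forest_cpp(X, y, as.integer(n_trees), as.integer(mtry),
                         as.integer(min_node), as.integer(seed),
                         as.numeric(lo), as.numeric(hi), as.integer(n_bins),
                         return_splits)
  oob_frac <- fit$n_oob / length(y)
  flagged <- oob_frac < 0.5
  if (flagged) {
    r2 <- 0
  } else {
    has <- !is.na(fit$oob_pred)
    mse <- mean((y[has] - fit$oob_pred[has])^2)
    r2 <- 1 - mse / mean((y - mean(y))^2)
  }
  imp <- stats::setNames(as.numeric(fit$importance), colnames(X))
  bi <- fit$bin_importance
  dimnames(bi) <- list(colnames(X), NULL)
  out <- list(snp_id = snp_id, oob_r2 = r2, oob_fraction = oob_frac,
              flagged = flagged, importance = imp, bin_importance = bi,
              bin_ranges = rbind(lo = lo, hi = hi), n_cases = length(y),
              params = list(n_trees = n_trees, mtry = mtry,
                            min_node = min_node, seed = seed, n_bins = n_bins))
  if (return_splits) {
    sp <- tibble::as_tibble(fit$splits)
    sp$predictor <- colnames(X)[sp$var + 1L]
    out$splits <- sp[c("predictor", "value", "improvement")]
  }
  structure(out, class = "snp_forest")
}

#' @export
print.snp_forest <- function(x, ...) {
  cat(sprintf("<snp_forest> %s: OOB R^2 = %.4f (%d cases, %d trees)%s\n",
              x$snp_id, x$oob_r2, x$n_cases, x$params$n_trees,
              if (x$flagged) " [flagged: sparse OOB coverage]" else ""))
  invisible(x)
}
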