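#' Fit a gradient forest over all SNPs
#'
#' Fits one regression forest per SNP against the 20 climate predictors,
#' retains the SNPs with positive out-of-bag R^2 ("predictive" SNPs), and
#' aggregates their split importances into per-predictor binned raw-importance
#' densities I(x), data densities d(x), standardized importances
#' f(x) = I(x)/d(x), monotone cumulative-importance (turnover) functions, and
#' overall R^2-weighted predictor importances.
#'
#' Each retained SNP's out-of-bag R^2 is partitioned across predictors in
#' proportion to its per-predictor raw (sum-of-impurity-reduction) importance;
#' a predictor's overall importance is the mean partitioned share over
#' retained SNPs, so shares conserve R^2 exactly and aggregate turnover totals
#' equal overall importances by construction.
#'
#' @param g A [genotype_matrix()].
#' @param climate Climate tibble; if it has a `sample_id` column it is aligned
#'   to the genotype samples, otherwise rows must already correspond.
#' @param n_trees Trees per SNP forest (default 200).
#' @param mtry Predictors tried per split (default `floor(20/3)` = 6).
#' @param min_node Minimum samples per child node (default 5).
#' @param seed Master seed; per-SNP seeds are derived deterministically.
#' @param n_bins Equal-width bins per predictor for I(x)/d(x) (default 101).
#' @param density_floor Denominator floor for f(x), as a fraction of
#'   `max(d)` (default 0.01); floored bins are flagged.
#' @param min_cases Minimum complete cases per SNP; SNPs below it (or with
#'   constant dosages) are skipped with a log entry.
#' @param missing_ceiling Per-SNP missingness ceiling (see
#'   [filter_missingness()]).
#' @return An object of class `gf_model`; see [tidy.gf_model()],
#'   [glance.gf_model()], [overall_importance()], [cumulative_importance()].
#'   With zero retained SNPs the model is returned with `n_retained = 0`, all
#'   importances zero and flat turnover functions (not an error).
#' @export
fit_gradient_forest <- function(g, climate, n_trees = 200, mtry = NULL,
                                min_node = 5, seed = 1, n_bins = 101,
                                density_floor = 0.01, min_cases = 30,
                                missing_ceiling = 0.2) {
  stopifnot(inherits(g, "genotype_matrix"))
  if ("sample_id" %in% names(climate)) {
    idx <- match(sample_ids(g), climate$sample_id)
    if (anyNA(idx)) stop("climate table is missing sampled individuals",
                         call. = FALSE)
    climate <- climate[idx, ]
  } else if (nrow(climate) != nrow(g$dosages)) {
    stop("genotypes and climate table are misaligned", call. = FALSE)
  }
  check_climate_columns(climate)
  g <- filter_missingness(g, missing_ceiling)
  if (ncol(g$dosages) < 1) stop("no SNPs to fit", call. = FALSE)

  X <- as.matrix(climate[climate_variable_names()])
  p <- ncol(X)
  if (is.null(mtry)) mtry <- max(1L, floor(p / 3))
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  ranges <- rbind(lo = lo, hi = hi)

  snps <- snp_ids(g)
  n_snp <- length(snps)
  r2 <- rep(NA_real_, n_snp)
  oob_frac <- rep(NA_real_, n_snp)
  flagged <- rep(FALSE, n_snp)
  status <- rep("fit", n_snp)
  imp_mat <- matrix(0, n_snp, p, dimnames = list(snps, colnames(X)))
  agg_bin <- matrix(0, p, n_bins, dimnames = list(colnames(X), NULL))
  shares <- matrix(0, n_snp, p, dimnames = list(snps, colnames(X)))

  for (i in seq_len(n_snp)) {
    dos <- g$dosages[, i]
    ok <- !is.na(dos)
    if (sum(ok) < min_cases || stats::var(dos[ok]) == 0) {
      status[i] <- if (sum(ok) < min_cases) "too_few_cases" else "monomorphic"
      next
    }
    fit <- .fit_forest_cpp(X[ok, , drop = FALSE], as.numeric(dos[ok]),
                           as.integer(n_trees), as.integer(mtry),
                           as.integer(min_node),
                           derive_seed(seed, paste0("snp_forest_", i)),
                           lo, hi, as.integer(n_bins), FALSE)
    frac <- fit$n_oob / sum(ok)
    oob_frac[i] <- frac
    if (frac < 0.5) {
      flagged[i] <- TRUE
      r2[i] <- 0
    } else {
      y <- as.numeric(dos[ok])
      has <- !is.na(fit$oob_pred)
      r2[i] <- 1 - mean((y[has] - fit$oob_pred[has])^2) /
        mean((y - mean(y))^2)
    }
    imp_mat[i, ] <- fit$importance
    tot <- sum(fit$importance)
    if (r2[i] > 0 && tot > 0) {
      shares[i, ] <- r2[i] * fit$importance / tot
      # each SNP's binned importances scaled to its partitioned R^2 share
      agg_bin <- agg_bin + fit$bin_importance * (r2[i] / tot)
    }
  }

  retained <- !is.na(r2) & r2 > 0 & rowSums(imp_mat) > 0
  n_retained <- sum(retained)
  if (sum(status != "fit") > 0) {
    gf_log("skipped %d SNP(s): %s", sum(status != "fit"),
           paste(unique(status[status != "fit"]), collapse = ", "))
  }
  if (n_retained == 0) {
    gf_log("no predictive SNPs (0 of %d with positive OOB R^2)", n_snp)
  } else {
    gf_log("retained %d of %d SNPs with positive OOB R^2 (%.1f%%); mean R^2 = %.4f",
           n_retained, n_snp, 100 * n_retained / n_snp, mean(r2[retained]))
  }

  overall <- if (n_retained > 0) colSums(shares[retained, , drop = FALSE]) /
    n_retained else stats::setNames(rep(0, p), colnames(X))
  agg_I <- if (n_retained > 0) agg_bin / n_retained else agg_bin

  widths <- (hi - lo) / n_bins
  density <- list()
  turnover <- list()
  for (v in colnames(X)) {
    edges <- seq(lo[v], hi[v], length.out = n_bins + 1)
    w <- widths[v]
    cnt <- if (w > 0) {
      b <- pmin(pmax(floor((X[, v] - lo[v]) / w) + 1, 1), n_bins)
      tabulate(b, n_bins)
    } else rep(0L, n_bins)
    d <- if (w > 0) cnt / (sum(cnt) * w) else rep(0, n_bins)
    std <- standardized_importance(agg_I[v, ], d, floor = density_floor)
    density[[v]] <- tibble::tibble(
      bin = seq_len(n_bins), lower = edges[-(n_bins + 1)], upper = edges[-1],
      mid = (edges[-(n_bins + 1)] + edges[-1]) / 2,
      d = d, I = agg_I[v, ], f = std$f, floored = std$flagged)
    turnover[[v]] <- turnover_from_binned(v, edges, std$f, overall[[v]])
  }

  fits <- tibble::tibble(
    snp_id = snps, status = status, oob_r2 = r2, oob_fraction = oob_frac,
    flagged = flagged, retained = unname(retained),
    total_importance = unname(rowSums(imp_mat)))

  structure(
    list(fits = fits, importance_matrix = imp_mat, shares = shares,
         overall_importance = overall, density = density, turnover = turnover,
         ranges = ranges, n_input_snps = n_snp, n_retained = n_retained,
         mean_r2 = if (n_retained > 0) mean(r2[retained]) else NA_real_,
         min_r2 = if (n_retained > 0) min(r2[retained]) else NA_real_,
         max_r2 = if (n_retained > 0) max(r2[retained]) else NA_real_,
         set_label = g$set_label,
         params = list(n_trees = n_trees, mtry = mtry, min_node = min_node,
                       seed = seed, n_bins = n_bins,
                       density_floor = density_floor, min_cases = min_cases,
                       missing_ceiling = missing_ceiling)),
    class = "gf_model")
}

#' @export
print.gf_model <- function(x, ...) {
  cat(sprintf("<gf_model> %d/%d SNPs retained (positive OOB R^2, %.1f%%); %d trees\n",
              x$n_retained, x$n_input_snps,
              100 * x$n_retained / max(x$n_input_snps, 1), x$params$n_trees))
  if (x$n_retained > 0) {
    top <- utils::head(overall_importance(x), 3)
    cat("  top predictors:",
        paste(sprintf("%s (%.4f)", top$predictor, top$importance),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Raw importance density I(x) for one predictor
#'
#' Accumulates the split-impurity reductions of retained SNP forests on one
#' predictor into equal-width bins over its observed range, each SNP's splits
#' pre-scaled to its partitioned R^2 share, divided by the number of retained
#' SNPs.
#'
#' @param fits List of `snp_forest` objects (the retained fits) **or** a
#'   `gf_model` (in which case the stored density is returned).
#' @param predictor Predictor name.
#' @param weights Optional per-fit scaling; defaults to
#'   `oob_r2 / total importance` per fit (R^2 partitioning).
#' @return Tibble with bin edges and the `I` density column.
#' @export
raw_importance_density <- function(fits, predictor, weights = NULL) {
  if (inherits(fits, "gf_model")) {
    return(fits$density[[predictor]][c("bin", "lower", "upper", "mid", "I")])
  }
  stopifnot(length(fits) >= 1)
  f1 <- fits[[1]]
  n_bins <- ncol(f1$bin_importance)
  lo <- f1$bin_ranges["lo", predictor]
  hi <- f1$bin_ranges["hi", predictor]
  acc <- rep(0, n_bins)
  for (k in seq_along(fits)) {
    ft <- fits[[k]]
    wk <- if (!is.null(weights)) weights[k] else {
      tot <- sum(ft$importance)
      if (tot > 0) ft$oob_r2 / tot else 0
    }
    acc <- acc + ft$bin_importance[predictor, ] * wk
  }
  acc <- acc / length(fits)
  edges <- seq(lo, hi, length.out = n_bins + 1)
  tibble::tibble(bin = seq_len(n_bins), lower = edges[-(n_bins + 1)],
                 upper = edges[-1],
                 mid = (edges[-(n_bins + 1)] + edges[-1]) / 2, I = acc)
}

#' Density-standardized importance f(x) = I(x) / d(x)
#'
#' Divides the raw importance density by the data density with a floored
#' denominator: bins where `d` falls below `floor * max(d)` use the floor and
#' are flagged, preventing importance blow-ups in data-sparse predictor
#' ranges.
#'
#' @param I Binned raw importance density (non-negative vector).
#' @param d Binned data density on the same binning (integrates to 1).
#' @param floor Denominator floor as a fraction of `max(d)` (default 0.01).
#' @return List with `f` (non-negative vector) and `flagged` (logical vector
#'   of floored bins).
#' @export
standardized_importance <- function(I, d, floor = 0.01) {
  if (length(I) != length(d)) stop("I and d are on different binnings",
                                   call. = FALSE)
  if (any(I < 0) || any(d < 0)) stop("densities must be non-negative",
                                     call. = FALSE)
  dmax <- max(d)
  if (dmax == 0) return(list(f = rep(0, length(I)), flagged = rep(TRUE, length(I))))
  flo <- floor * dmax
  flagged <- d < flo
  list(f = I / pmax(d, flo), flagged = flagged)
}

# ---- turnover functions -----------------------------------------------------

new_turnover_function <- function(predictor, breakpoints, cumimp, range) {
  stopifnot(length(breakpoints) == length(cumimp),
            !is.unsorted(breakpoints),
            all(diff(cumimp) >= -1e-12))
  cumimp <- cummax(pmax(cumimp, 0))  # clip numeric dust; stays monotone
  structure(list(predictor = predictor, breakpoints = breakpoints,
                 cumimp = cumimp, total = cumimp[length(cumimp)],
                 range = range),
            class = "turnover_function")
}

turnover_from_binned <- function(predictor, edges, f, total) {
  w <- diff(edges)
  inc <- f * w
  s <- sum(inc)
  cum <- if (s > 0 && total > 0) c(0, cumsum(inc)) * (total / s)
         else rep(0, length(edges))
  new_turnover_function(predictor, edges, cum, range(edges))
}

turnover_from_splits <- function(predictor, values, weights, range, total = NULL) {
  if (length(values) == 0) {
    return(new_turnover_function(predictor, range, c(0, 0), range))
  }
  o <- order(values)
  values <- values[o]; weights <- weights[o]
  agg <- rowsum(weights, group = values, reorder = TRUE)
  bp <- as.numeric(rownames(agg))
  cum <- cumsum(as.numeric(agg))
  if (!is.null(total) && cum[length(cum)] > 0) {
    cum <- cum * (total / cum[length(cum)])
  }
  bp <- c(range[1], bp)
  cum <- c(0, cum)
  if (bp[2] == bp[1]) { bp <- bp[-1]; cum <- cum[-1] }
  new_turnover_function(predictor, bp, cum, range)
}

#' Cumulative-importance (turnover) functions
#'
#' The turnover function of a predictor is the monotone non-decreasing
#' cumulative importance along its gradient: steep segments mark predictor
#' ranges of rapid allelic compositional change. For a `gf_model` the
#' aggregate curve is the cumulative integral of the density-standardized
#' importance f(x), rescaled so its right-endpoint total equals the
#' predictor's overall R^2-weighted importance. For a single `snp_forest`
#' (fit with `return_splits = TRUE`) the curve is the staircase tally of that
#' SNP's split-impurity reductions, rescaled to the SNP's per-predictor
#' importance share.
#'
#' @param x A `gf_model`, `snp_forest`, or a data frame of split events with
#'   columns `predictor`, `value`, `improvement`.
#' @param predictor Predictor name.
#' @param ... Passed on to methods.
#' @return A `turnover_function`; evaluate it with [predict.turnover_function()].
#' @export
cumulative_importance <- function(x, predictor, ...) {
  UseMethod("cumulative_importance")
}

#' @export
cumulative_importance.gf_model <- function(x, predictor, ...) {
  tf <- x$turnover[[predictor]]
  if (is.null(tf)) stop(sprintf("unknown predictor %s", predictor), call. = FALSE)
  tf
}

#' @rdname cumulative_importance
#' @param rescale_to Right-endpoint total for the curve: `"share"` (default)
#'   rescales to the SNP's partitioned R^2 share for the predictor, `"none"`
#'   keeps the raw summed improvements, a number forces that total.
#' @export
cumulative_importance.snp_forest <- function(x, predictor,
                                             rescale_to = "share", ...) {
  if (is.null(x$splits)) {
    stop("fit the forest with return_splits = TRUE for per-SNP turnover",
         call. = FALSE)
  }
  if (identical(rescale_to, "none")) {
    rescale_to <- NULL
  } else if (identical(rescale_to, "share")) {
    tot <- sum(x$importance)
    rescale_to <- if (tot > 0) x$oob_r2 * x$importance[[predictor]] / tot
                  else 0
    if (rescale_to <= 0) rescale_to <- NULL
  }
  sp <- x$splits[x$splits$predictor == predictor, ]
  turnover_from_splits(predictor, sp$value, sp$improvement,
                       range = as.numeric(x$bin_ranges[, predictor]),
                       total = rescale_to)
}

#' @export
cumulative_importance.data.frame <- function(x, predictor, rescale_to = NULL,
                                             range = NULL, ...) {
  sp <- x[x$predictor == predictor, ]
  if (is.null(range)) {
    range <- if (nrow(sp) > 0) base::range(sp$value) else c(0, 1)
  }
  turnover_from_splits(predictor, sp$value, sp$improvement, range = range,
                       total = rescale_to)
}

#' Evaluate a turnover function
#'
#' @param object A `turnover_function`.
#' @param x Numeric vector of predictor values.
#' @param rule `"linear"` interpolates between breakpoints (the default used
#'   for grid transformation); `"staircase"` is right-continuous step
#'   evaluation (the sum of importance at split values `<= x`).
#' @param ... Unused.
#' @return Numeric vector: 0 below the observed range, the total above it.
#' @export
predict.turnover_function <- function(object, x, rule = c("linear", "staircase"),
                                      ...) {
  rule <- match.arg(rule)
  bp <- object$breakpoints
  cv <- object$cumimp
  if (length(bp) == 1 || object$total == 0) {
    return(ifelse(x < object$range[1], 0,
                  ifelse(x >= object$range[2], object$total,
                         rep(object$total, length(x)))))
  }
  if (rule == "linear") {
    stats::approx(bp, cv, xout = x, method = "linear", rule = 2,
                  ties = "ordered")$y
  } else {
    stats::approx(bp, cv, xout = x, method = "constant", f = 0,
                  yleft = 0, yright = object$total, ties = "ordered")$y
  }
}

#' @export
print.turnover_function <- function(x, ...) {
  cat(sprintf("<turnover_function> %s: total %.5f over [%.4g, %.4g] (%d breakpoints)\n",
              x$predictor, x$total, x$range[1], x$range[2],
              length(x$breakpoints)))
  invisible(x)
}

#' Overall predictor importance
#'
#' Each retained SNP's OOB R^2 is partitioned across predictors proportional
#' to its per-predictor raw split importance; a predictor's overall importance
#' is the mean partitioned share over retained SNPs. Sorted descending, ties
#' broken alphabetically.
#'
#' @param model A `gf_model`.
#' @return Tibble with `predictor`, `importance`, `rank`.
#' @export
overall_importance <- function(model) {
  stopifnot(inherits(model, "gf_model"))
  imp <- model$overall_importance
  ord <- order(-imp, names(imp), method = "radix")
  tibble::tibble(predictor = names(imp)[ord],
                 importance = as.numeric(imp[ord]),
                 rank = seq_along(imp))
}

# ---- broom-style accessors --------------------------------------------------

#' Tidy a gradient forest model
#'
#' @param x A `gf_model`.
#' @param what `"importance"` (default): per-predictor overall importance;
#'   `"snps"`: the per-SNP fit table; `"turnover"`: long tibble of all
#'   turnover-curve breakpoints; `"density"`: long tibble of the binned
#'   d/I/f densities.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.gf_model <- function(x, what = c("importance", "snps", "turnover",
                                      "density"), ...) {
  what <- match.arg(what)
  switch(what,
    importance = overall_importance(x),
    snps = x$fits,
    turnover = purrr::map_dfr(x$turnover, function(tf) {
      tibble::tibble(predictor = tf$predictor, value = tf$breakpoints,
                     cumulative_importance = tf$cumimp)
    }),
    density = purrr::map_dfr(names(x$density), function(v) {
      dplyr::mutate(x$density[[v]], predictor = v, .before = 1)
    })
  )
}

#' One-row model summary
#'
#' @param x A `gf_model`.
#' @param ... Unused.
#' @return A one-row tibble: SNP counts, retention rate, R^2 summaries, and
#'   fitting metadata.
#' @export
glance.gf_model <- function(x, ...) {
  tibble::tibble(
    n_input_snps = x$n_input_snps, n_retained = x$n_retained,
    retention_rate = x$n_retained / max(x$n_input_snps, 1),
    mean_r2 = x$mean_r2, min_r2 = x$min_r2, max_r2 = x$max_r2,
    n_trees = x$params$n_trees, mtry = x$params$mtry,
    n_bins = x$params$n_bins, seed = x$params$seed)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

# ---- serialization ----------------------------------------------------------

#' Export / import a fitted gradient forest model as JSON + CSV
#'
#' The JSON container holds metadata, overall importances and every turnover
#' curve as breakpoint/value arrays; the per-SNP fit table goes to a CSV
#' sidecar. Densities are recomputable from the fits and are included in the
#' JSON for plotting convenience.
#'
#' @param model A `gf_model`.
#' @param path Output `.json` path (`<path>.snps.csv` sidecar is written next
#'   to it).
#' @return `path`, invisibly (`write_gf_model`); a reduced `gf_model` with
#'   curves, importances and fit table (`read_gf_model`).
#' @export
write_gf_model <- function(model, path) {
  stopifnot(inherits(model, "gf_model"))
  side <- paste0(sub("\\.json$", "", path), ".snps.csv")
  utils::write.csv(model$fits, side, row.names = FALSE)
  payload <- list(
    params = model$params, n_input_snps = model$n_input_snps,
    n_retained = model$n_retained, mean_r2 = model$mean_r2,
    min_r2 = model$min_r2, max_r2 = model$max_r2,
    set_label = model$set_label,
    ranges = as.data.frame(model$ranges),
    overall_importance = as.list(model$overall_importance),
    turnover = lapply(model$turnover, function(tf) {
      list(predictor = tf$predictor, breakpoints = tf$breakpoints,
           cumimp = tf$cumimp, range = tf$range)
    }),
    density = lapply(model$density, as.data.frame),
    snp_table = basename(side))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gf_model
#' @export
read_gf_model <- function(path) {
  pl <- jsonlite::read_json(path, simplifyVector = TRUE)
  fits <- tibble::as_tibble(
    utils::read.csv(file.path(dirname(path), pl$snp_table)))
  turnover <- lapply(pl$turnover, function(tf) {
    new_turnover_function(tf$predictor, tf$breakpoints, tf$cumimp, tf$range)
  })
  density <- lapply(pl$density, tibble::as_tibble)
  structure(
    list(fits = fits, overall_importance = unlist(pl$overall_importance),
         density = density, turnover = turnover,
         ranges = as.matrix(pl$ranges),
         n_input_snps = pl$n_input_snps, n_retained = pl$n_retained,
         mean_r2 = pl$mean_r2, min_r2 = pl$min_r2, max_r2 = pl$max_r2,
         set_label = pl$set_label, params = pl$params),
    class = "gf_model")
}
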