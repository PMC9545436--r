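#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot overall predictor importance
#'
#' Horizontal bar chart of R^2-weighted overall importance, most important
#' predictor on top.
#'
#' @param object A `gf_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gf_model
#' @export
autoplot.gf_model <- function(object, ...) {
  imp <- overall_importance(object)
  ggplot2::ggplot(imp, ggplot2::aes(
      x = .data$importance,
      y = stats::reorder(.data$predictor, .data$importance))) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = expression(R^2 * "-weighted importance"), y = NULL,
                  title = sprintf("Overall predictor importance (%d/%d SNPs retained)",
                                  object$n_retained, object$n_input_snps)) +
    ggplot2::theme_minimal()
}

#' Turnover curves for selected predictors
#'
#' @param model A `gf_model`.
#' @param predictors Predictor names (default: top 4 by overall importance).
#' @return A ggplot of cumulative-importance curves, one facet per predictor.
#' @export
plot_turnover <- function(model, predictors = NULL) {
  if (is.null(predictors)) {
    predictors <- utils::head(overall_importance(model)$predictor, 4)
  }
  df <- tidy(model, "turnover") |>
    dplyr::filter(.data$predictor %in% predictors) |>
    dplyr::mutate(predictor = factor(.data$predictor, levels = predictors))
  ggplot2::ggplot(df, ggplot2::aes(.data$value, .data$cumulative_importance)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~predictor, scales = "free_x") +
    ggplot2::labs(x = "predictor value", y = "cumulative importance") +
    ggplot2::theme_minimal()
}

#' Split-density panels (d, I and f) for one predictor
#'
#' Mirrors the classic gradient-forest diagnostic: binned raw importance
#' density I(x), data density d(x) and their ratio f(x) = I(x)/d(x) along one
#' predictor's gradient.
#'
#' @param model A `gf_model`.
#' @param predictor Predictor name.
#' @return A ggplot.
#' @export
plot_split_density <- function(model, predictor) {
  d <- model$density[[predictor]]
  if (is.null(d)) stop(sprintf("unknown predictor %s", predictor), call. = FALSE)
  long <- tidyr::pivot_longer(d, c("d", "I", "f"), names_to = "curve")
  ggplot2::ggplot(long, ggplot2::aes(.data$mid, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~curve, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = predictor, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a cluster scan: W(k) and its reductions
#'
#' Within-cluster variation (line) with per-k reduction (bars), the display
#' used to choose the operational number of zones.
#'
#' @param object A `cluster_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cluster_scan
#' @export
autoplot.cluster_scan <- function(object, ...) {
  sc <- object$scan
  ggplot2::ggplot(sc, ggplot2::aes(.data$k)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$reduction), fill = "grey70",
                      na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$W)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$W)) +
    ggplot2::labs(x = "number of clusters k",
                  y = "within-cluster variation (line) / reduction (bars)") +
    ggplot2::theme_minimal()
}

#' Map a zone delineation
#'
#' @param object A `zone_map`.
#' @param ... Unused.
#' @return A ggplot raster of zone labels.
#' @method autoplot zone_map
#' @export
autoplot.zone_map <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$x, .data$y,
                               fill = factor(.data$zone))) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "zone") +
    ggplot2::theme_minimal()
}

#' Map an RGB genomic-composition surface
#'
#' @param rgb Output of [rgb_map()].
#' @return A ggplot raster colored by the PC1-PC3 palette.
#' @export
plot_rgb_map <- function(rgb) {
  ggplot2::ggplot(rgb, ggplot2::aes(.data$x, .data$y, fill = .data$hex)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_identity() +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
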