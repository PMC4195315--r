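#' Turn a result object into a tidy tibble
#'
#' Broom-style generic: one row per voxel (or per summary unit) with the
#' result's provenance columns alongside the values.
#'
#' @param x a result object (`threshold_report`, `degree_result`,
#'   `reliability_result`, ...).
#' @param ... passed to methods.
#' @return a tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row summary of a result object
#'
#' @inheritParams tidy
#' @return a one-row tibble.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Histogram of a degree map
#'
#' @param object a `degree_result`.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.degree_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "grey20") +
    ggplot2::labs(
      x = sprintf("%s%s at T_d = %.2f", object$metric,
                  if (object$corrected) "_RSE" else "", object$T_d),
      y = "voxels") +
    ggplot2::theme_minimal()
}

#' Mean degree across the threshold sweep
#'
#' @param object a `degree_sweep` tibble from [threshold_sweep()].
#' @param ... ignored.
#' @return a ggplot of mask-mean degree vs threshold, by metric and
#'   correction.
#' @export
autoplot.degree_sweep <- function(object, ...) {
  df <- dplyr::summarise(
    dplyr::group_by(object, .data$metric, .data$T_d, .data$corrected),
    mean_value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$T_d, y = .data$mean_value,
                                   colour = .data$metric,
                                   linetype = .data$corrected)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "connectivity threshold T_d", y = "mask-mean degree") +
    ggplot2::theme_minimal()
}

#' Reliability across the threshold sweep
#'
#' @param object a `reliability_sweep` tibble from [reliability_sweep()].
#' @param ... ignored.
#' @return a ggplot of mask-mean ICC vs threshold.
#' @export
autoplot.reliability_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$T_d, y = .data$mean_icc,
                                       colour = .data$metric,
                                       linetype = .data$corrected)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "connectivity threshold T_d",
                  y = "mask-mean test-retest ICC") +
    ggplot2::theme_minimal()
}
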