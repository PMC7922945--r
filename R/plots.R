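#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot velocity--time curves
#'
#' One panel per velocity direction with a line per region.
#'
#' @param object An `mvm_curves` tibble from [compute_curves()].
#' @param regions Regions to show (default global only).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mvm_curves <- function(object, regions = "global", ...) {
  df <- dplyr::filter(object, .data$region %in% regions)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$velocity_cm_s,
                                   colour = .data$region)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~direction, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time (ms)", y = "Velocity (cm/s)", colour = "Region") +
    ggplot2::theme_minimal()
}

#' @export
plot.mvm_curves <- function(x, ...) print(autoplot(x, ...))

#' Plot a Bland-Altman analysis
#'
#' Scatter of pair differences against pair means, with the bias and 95%
#' limits of agreement.
#'
#' @param object An `mvm_bland_altman` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mvm_bland_altman <- function(object, ...) {
  df <- tibble::tibble(mean = object$means, diff = object$diffs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        colour = "indianred", linetype = "dashed") +
    ggplot2::labs(x = "Mean of pair", y = "Difference (y - x)") +
    ggplot2::theme_minimal()
}

#' @export
plot.mvm_bland_altman <- function(x, ...) print(autoplot(x, ...))

#' Plot extracted contours over a mask frame
#'
#' @param object An `mvm_contours` tibble from [extract_contours()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mvm_contours <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x_px, y = .data$y_px,
                                       colour = .data$contour)) +
    ggplot2::geom_path() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
plot.mvm_contours <- function(x, ...) print(autoplot(x, ...))
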