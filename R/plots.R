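#' Boxplot of trap optical volumes with the 1.5 x IQR outlier rule
#'
#' @param values Numeric vector (e.g. empty-trap optical volumes).
#' @param ylab Axis label.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_volume_boxplot <- function(values, ylab = "optical volume (um^3)") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  d <- data.frame(x = "", y = values)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_boxplot(coef = 1.5, outlier.shape = 3,
                          outlier.colour = "red") +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_classic()
}

#' Mean normalized cell mass versus time
#'
#' @param average Data frame from [normalize_and_average()].
#' @param fit Optional fit from [fit_growth_rate()]; when given, the fitted
#'   exponential is overlaid.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_growth <- function(average, fit = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  p <- ggplot2::ggplot(average,
                       ggplot2::aes(x = .data$time_h,
                                    y = .data$mean_normalized_mass)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "normalized mass") +
    ggplot2::theme_classic()
  if (!is.null(fit)) {
    curve <- data.frame(time_h = average$time_h)
    curve$mean_normalized_mass <- exp(fit$rate * curve$time_h)
    p <- p + ggplot2::geom_line(data = curve, linetype = "dashed",
                                colour = "red")
  }
  p
}
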