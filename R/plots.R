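#' Bland-Altman plot for one gait metric
#'
#' Difference (reference minus test) against the pairwise mean, with the mean
#' difference (blue) and the +/- 1.96 SD limits of agreement (red); points
#' inside the limits are drawn green, points outside yellow.
#'
#' @param x,y paired per-subject values from the reference and test device.
#' @param metric metric name for the title.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(x, y, metric = "metric") {
  ba <- bland_altman(x, y)
  df <- data.frame(m = (x + y) / 2, d = x - y)
  df$outside <- df$d < ba$loa_lower | df$d > ba$loa_upper
  ggplot2::ggplot(df, ggplot2::aes(x = .data$m, y = .data$d)) +
    ggplot2::geom_hline(yintercept = ba$mean_diff, colour = "blue") +
    ggplot2::geom_hline(yintercept = c(ba$loa_lower, ba$loa_upper),
                        colour = "red", linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$outside), size = 2,
                        show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "darkgreen",
                                            `TRUE` = "goldenrod2")) +
    ggplot2::labs(title = paste("Bland-Altman:", metric),
                  x = "Mean of both devices",
                  y = "Difference (reference - test)") +
    ggplot2::theme_minimal()
}

#' Scatter plot of test against reference values
#'
#' @inheritParams plot_bland_altman
#' @return A ggplot object with the identity line.
#' @export
plot_scatter <- function(x, y, metric = "metric") {
  df <- data.frame(ref = x, test = y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ref, y = .data$test)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_point(colour = "steelblue", size = 2) +
    ggplot2::labs(title = paste("Scatter:", metric),
                  x = "Reference device", y = "Test device") +
    ggplot2::theme_minimal()
}
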