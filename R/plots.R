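#' Histogram of normalized screen values with the null-model overlay
#'
#' The screen's distribution of per-strain normalized log2 ratios, with the
#' Gaussian null model drawn on top and the calling threshold marked; the
#' right tail beyond the threshold is the hit population.
#'
#' @param ratios Tibble `strain_id`, `log2_ratio`.
#' @param model Optional [fit_null_model()] object to overlay.
#' @param threshold Calling threshold to mark (default 1.0).
#' @param binwidth Histogram bin width in log2 units (default 0.1).
#' @return A ggplot object.
#' @export
plot_screen_distribution <- function(ratios, model = NULL, threshold = 1.0,
                                     binwidth = 0.1) {
  assert_columns(ratios, c("log2_ratio"))
  p <- ggplot2::ggplot(ratios, ggplot2::aes(x = .data$log2_ratio)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(density)),
      binwidth = binwidth, fill = "grey75", colour = "grey45"
    ) +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(
      x = "normalized log2 reporter/housekeeping ratio",
      y = "density",
      title = "Screen distribution vs Gaussian null"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(model)) {
    grid <- seq(min(ratios$log2_ratio), max(ratios$log2_ratio),
                length.out = 400)
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(log2_ratio = grid,
                            density = dnorm(grid, model$mean, model$sd)),
      ggplot2::aes(y = .data$density),
      colour = "blue", linetype = "dotted", linewidth = 0.8
    )
  }
  p
}
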