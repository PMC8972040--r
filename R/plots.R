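#' Plot a fitted recovery curve over its data
#'
#' @param object A `frap_fit` from [fit_recovery()].
#' @param ... Unused.
#' @return A ggplot: normalized change magnitude versus time with the
#'   fitted exponential overlaid.
#' @export
autoplot.frap_fit <- function(object, ...) {
  dat <- tibble::as_tibble(object$data)
  grid <- tibble::tibble(t = seq(0, max(dat$t), length.out = 200))
  grid$y <- object$Mf * (1 - exp(-object$b * grid$t)) + object$c
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$t, y = .data$y)) +
    ggplot2::geom_point(size = 1, alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "steelblue", linewidth = 0.8) +
    ggplot2::labs(
      x = "time after photoconversion (h)",
      y = "normalized fluorescence change",
      title = sprintf("%s channel: Mf = %.3f, t1/2 = %.2f h",
                      object$channel, object$Mf, object$t_half)
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a red minus green difference map
#'
#' @param object A `difference_map` from [build_difference_map()].
#' @param ... Unused.
#' @return A ggplot tile map of the difference over normalized position and
#'   time, diverging around 0.
#' @export
autoplot.difference_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x_norm, y = .data$time_min,
                                       fill = .data$diff)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "darkgreen", mid = "black",
                                  high = "red", midpoint = 0,
                                  limits = c(-1, 1),
                                  name = "red - green") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "normalized distance from sarcomere center",
                  y = "time post-photoconversion (min)") +
    ggplot2::theme_minimal()
}

#' Stacked category-frequency bars per chase time
#'
#' @param object A `pattern_summary` from [summarize_patterns()].
#' @param ... Unused.
#' @return A ggplot stacked bar chart of the rolled-up category
#'   proportions.
#' @export
autoplot.pattern_summary <- function(object, ...) {
  roll <- object$rollup
  roll$group <- factor(roll$group,
                       levels = c("no_incorporation", "random_fashion",
                                  "center", "side_group"))
  ggplot2::ggplot(roll, ggplot2::aes(x = factor(.data$time_min),
                                     y = .data$mean_prop,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "chase time (min)", y = "mean proportion",
                  fill = "pattern group") +
    ggplot2::theme_minimal()
}

#' Overlay normalized sarcomere waveforms
#'
#' @param waveforms A long waveform tibble (see [waveform_table()]) or a
#'   list of `sarcomere_waveform` objects.
#' @return A ggplot overlaying the green and red normalized waveforms,
#'   faceted by time when several time points are present.
#' @export
plot_waveforms <- function(waveforms) {
  if (is.list(waveforms) && !is.data.frame(waveforms)) {
    waveforms <- waveform_table(waveforms)
  }
  long <- tidyr::pivot_longer(waveforms, c("green", "red"),
                              names_to = "channel", values_to = "intensity")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$x_norm,
                                          y = .data$intensity,
                                          colour = .data$channel,
                                          group = interaction(
                                            .data$channel,
                                            .data$sarcomere_id))) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_colour_manual(values = c(green = "darkgreen",
                                            red = "red3")) +
    ggplot2::labs(x = "normalized distance from sarcomere center",
                  y = "normalized intensity") +
    ggplot2::theme_minimal()
  if (length(unique(long$time_min)) > 1) {
    p <- p + ggplot2::facet_wrap(~time_min)
  }
  p
}

#' Histogram of red-peak distances from the sarcomere center
#'
#' @param summary A `pattern_summary` from [summarize_patterns()].
#' @return A ggplot histogram of `|x_peak|` per chase time.
#' @export
plot_peak_shift <- function(summary) {
  stopifnot(inherits(summary, "pattern_summary"))
  ggplot2::ggplot(summary$peak_shift,
                  ggplot2::aes(x = .data$shift, fill = .data$subcategory)) +
    ggplot2::geom_histogram(binwidth = summary$bin_width, boundary = 0,
                            colour = "grey30", linewidth = 0.1) +
    ggplot2::facet_wrap(~time_min, ncol = 1) +
    ggplot2::labs(x = "distance of red peak from center (normalized)",
                  y = "count", fill = "pattern") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
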