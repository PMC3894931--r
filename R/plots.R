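# Optional ggplot2 figures mirroring the standard summaries (accuracy bars,
# arrival-time histograms, trade-off curves).  ggplot2 is suggested, not
# imported.

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting; install it or use the CSV outputs")
  }
}

#' Plot an arrival-time histogram
#'
#' @param batch Batch data frame.
#' @param bin_width Bin width in seconds (default 0.1).
#' @param max_time_s Truncate the x axis (default 60 s) for visibility.
#' @return A ggplot object.
#' @export
plot_arrival_histogram <- function(batch, bin_width = 0.1, max_time_s = 60) {
  need_ggplot()
  h <- arrival_histogram(batch, bin_width)
  h <- h[h$bin_start < max_time_s, , drop = FALSE]
  ggplot2::ggplot(h, ggplot2::aes(x = bin_start, y = count)) +
    ggplot2::geom_col(width = bin_width) +
    ggplot2::labs(x = "arrival time to periphery (s)", y = "runs")
}

#' Plot the speed-accuracy trade-off
#'
#' @param curve Output of [tradeoff_curve()].
#' @return A ggplot object with arrival time and accuracy against speed.
#' @export
plot_tradeoff <- function(curve) {
  need_ggplot()
  long <- rbind(
    data.frame(speed = curve$speed, value = curve$mean_time,
               panel = "mean arrival time (s)"),
    data.frame(speed = curve$speed, value = 100 * curve$accuracy_exact,
               panel = "arrival accuracy (%)"))
  ggplot2::ggplot(long, ggplot2::aes(x = speed, y = value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "walking speed (m/s)", y = NULL)
}
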