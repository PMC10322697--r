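## QC figures. All return ggplot objects.

#' Movement-versus-rest PSD pair for one channel
#'
#' Mean normalized PSD during one movement's trials and during the rest
#' trials following it, on log-log axes with the analysis band shaded —
#' broadband increase above 65 Hz and the 10-30 Hz decrease are read directly
#' off this plot.
#'
#' @param tpsd a [trial_psd()] object.
#' @param channel channel name.
#' @param movement movement type.
#' @param band band to shade.
#' @return ggplot.
#' @export
plot_psd_pair <- function(tpsd, channel, movement = "hand", band = c(65, 115)) {
  i <- match(channel, tpsd$channels)
  if (is.na(i)) abort(sprintf("unknown channel '%s'", channel))
  ep <- tpsd$epochs
  mv <- ep$trial_type == movement
  rs <- ep$trial_type == "rest" & !is.na(ep$follows) & ep$follows == movement
  df <- dplyr::bind_rows(
    tibble(freq = tpsd$freq, power = colMeans(tpsd$psd[i, mv, , drop = TRUE]),
           condition = movement),
    tibble(freq = tpsd$freq, power = colMeans(tpsd$psd[i, rs, , drop = TRUE]),
           condition = "rest"))
  ggplot2::ggplot(df, ggplot2::aes(.data$freq, .data$power, colour = .data$condition)) +
    ggplot2::annotate("rect", xmin = band[1], xmax = band[2], ymin = -Inf, ymax = Inf,
                      alpha = 0.15) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "normalized power", title = channel)
}

#' Somatotopy map scatter
#'
#' Tuning angle against vector magnitude; point size scales with shared
#' overlap so shared-representation channels (small magnitude, large overlap)
#' stand apart from somatotopic ones.
#'
#' @param map tibble from [threshold_maps()].
#' @return ggplot.
#' @export
plot_somatotopy <- function(map) {
  ggplot2::ggplot(map, ggplot2::aes(.data$angle, .data$magnitude,
                                    size = .data$overlap)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_polar() +
    ggplot2::scale_x_continuous(limits = c(0, 2 * pi),
                                breaks = c(pi / 6, 5 * pi / 6, 3 * pi / 2),
                                labels = c("hand", "tongue", "foot")) +
    ggplot2::labs(x = NULL, y = "|tuning|", size = "overlap")
}

#' @method autoplot cluster_selection
#' @export
autoplot.cluster_selection <- function(object, ...) {
  pc <- object$penalty_curve
  ggplot2::ggplot(pc, ggplot2::aes(.data$k, .data$penalty)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$votes)) +
    ggplot2::geom_vline(xintercept = object$k_selected, linetype = 2) +
    ggplot2::labs(x = "number of clusters",
                  y = sprintf("k^%.2g x within-cluster SS", object$alpha),
                  size = "restart votes")
}

#' Latency histogram
#'
#' Brain-EMG peak lags; positive lags mean brain activity precedes EMG.
#'
#' @param latencies tibble from [estimate_latency()].
#' @return ggplot.
#' @export
plot_latency_hist <- function(latencies) {
  ggplot2::ggplot(latencies, ggplot2::aes(.data$lag_ms)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~.data$effector) +
    ggplot2::labs(x = "brain leads EMG by (ms)", y = "channel pairs")
}

#' @method autoplot decoding_result
#' @export
autoplot.decoding_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth, fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::facet_wrap(~.data$group) +
    ggplot2::labs(x = "predicted", y = "true class")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
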