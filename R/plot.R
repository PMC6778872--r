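## long format shared by the channel plots
.channels_long <- function(df) {
  df |>
    dplyr::select("time_s", "eda_us", "temp_c", "hr_bpm") |>
    tidyr::pivot_longer(-"time_s", names_to = "channel",
                        values_to = "value") |>
    dplyr::mutate(channel = factor(.data$channel,
                                   levels = c("eda_us", "temp_c", "hr_bpm"),
                                   labels = c("EDA (µS)",
                                              "Temperature (°C)",
                                              "Heart rate (bpm)")))
}

#' Plot the three channels of a raw recording
#'
#' @param object A [physio_recording()].
#' @param ... Unused.
#' @return A ggplot object, one facet per channel.
#' @method autoplot physio_recording
#' @export
autoplot.physio_recording <- function(object, ...) {
  ggplot2::ggplot(.channels_long(object),
                  ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = NULL,
                  title = attr(object, "session_id")) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.physio_recording
#' @method autoplot clean_signals
#' @export
autoplot.clean_signals <- function(object, ...) {
  autoplot.physio_recording(object, ...)
}

#' Plot signal-quality series with the validity mask
#'
#' @param object An `sqi_series` from [compute_sqi()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sqi_series
#' @export
autoplot.sqi_series <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(c("sqi_eda", "sqi_temp", "sqi_all"),
                        names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::facet_wrap(~series, ncol = 1) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Time (s)", y = "SQI") +
    ggplot2::theme_minimal()
}

#' Overlay detected events on the cleaned channels
#'
#' Shades each event's video-clip window and marks the event time on the
#' channel of its dominant modality.
#'
#' @param clean A `clean_signals` tibble.
#' @param events An [event_table()].
#' @return A ggplot object.
#' @export
plot_events <- function(clean, events) {
  long <- .channels_long(clean)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s,
                                          y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = NULL) +
    ggplot2::theme_minimal()
  if (nrow(events) > 0) {
    clips <- tibble::tibble(clip_start_s = events$clip_start_s,
                            clip_end_s = events$clip_end_s)
    p <- p +
      ggplot2::geom_rect(data = clips,
                         ggplot2::aes(xmin = .data$clip_start_s,
                                      xmax = .data$clip_end_s),
                         ymin = -Inf, ymax = Inf, alpha = 0.15,
                         fill = "red", inherit.aes = FALSE) +
      ggplot2::geom_vline(xintercept = events$time_s,
                          linetype = "dashed", colour = "red",
                          linewidth = 0.3)
  }
  p
}
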