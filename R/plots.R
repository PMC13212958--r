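#' Plot a stretch of the raw recording
#'
#' One facet per channel, potentials against time, with optional detected
#' spike onsets overlaid.
#'
#' @param rec a `recording`.
#' @param t0,t1 window bounds in seconds (default: full recording).
#' @param spikes optional spike tibble whose onsets are marked.
#' @return a ggplot object.
#' @export
plot_recording <- function(rec, t0 = NULL, t1 = NULL, spikes = NULL) {
  t0 <- t0 %||% min(rec$time_s)
  t1 <- t1 %||% max(rec$time_s)
  long <- tibble::as_tibble(rec) |>
    dplyr::filter(.data$time_s >= t0, .data$time_s <= t1) |>
    tidyr::pivot_longer(-"time_s", names_to = "channel",
                        values_to = "potential_mV") |>
    dplyr::mutate(channel = factor(.data$channel,
                                   levels = channel_labels(rec)))
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time_s,
                                          .data$potential_mV)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "time (s)", y = "potential (mV)")
  if (!is.null(spikes) && nrow(spikes) > 0) {
    sp <- dplyr::filter(spikes, .data$onset_s >= t0, .data$onset_s <= t1) |>
      dplyr::mutate(channel = factor(.data$channel,
                                     levels = channel_labels(rec)))
    p <- p + ggplot2::geom_vline(data = sp,
                                 ggplot2::aes(xintercept = .data$onset_s),
                                 colour = "firebrick", linetype = "dashed",
                                 linewidth = 0.3)
  }
  p
}

#' Raster plot of spike onsets across channels
#'
#' @param spikes tibble with `channel` and `onset_s` columns.
#' @param t0,t1 optional window bounds in seconds.
#' @return a ggplot object.
#' @export
plot_raster <- function(spikes, t0 = NULL, t1 = NULL) {
  t0 <- t0 %||% min(spikes$onset_s)
  t1 <- t1 %||% max(spikes$onset_s)
  d <- raster_data(spikes, t0, t1)
  ggplot2::ggplot(d, ggplot2::aes(.data$onset_s, .data$channel)) +
    ggplot2::geom_point(shape = "|", size = 4) +
    ggplot2::labs(x = "onset time (s)", y = NULL)
}

#' @describeIn average_spike_shape mean waveform with interquartile band.
#' @param object a `spike_shape`.
#' @param ... unused.
#' @method autoplot spike_shape
#' @export
autoplot.spike_shape <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::labs(x = "time from onset (s)",
                  y = "peak-normalised potential",
                  subtitle = sprintf("%d events", attr(object, "n_events")))
}

#' @describeIn lead_lag_matrix heatmap of median lead-lag delays.
#' @param object a `delay_matrix`.
#' @param ... unused.
#' @method autoplot delay_matrix
#' @export
autoplot.delay_matrix <- function(object, ...) {
  tidy(object) |>
    dplyr::mutate(
      lead_channel = factor(.data$lead_channel, levels = object$channels),
      lag_channel = factor(.data$lag_channel, levels = object$channels)
    ) |>
    ggplot2::ggplot(ggplot2::aes(.data$lag_channel, .data$lead_channel,
                                 fill = .data$median_delay_s)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", high = "firebrick",
                                  na.value = "grey90") +
    ggplot2::labs(x = "lag channel", y = "lead channel",
                  fill = "median\ndelay (s)")
}

#' @describeIn fit_velocity median delay against distance with the fitted
#'   Theil-Sen line.
#' @param object a `velocity_fit`.
#' @param ... unused.
#' @method autoplot velocity_fit
#' @export
autoplot.velocity_fit <- function(object, ...) {
  d <- dplyr::filter(object$data, !is.na(.data$median_delay_s))
  ggplot2::ggplot(d, ggplot2::aes(.data$distance_cm,
                                  .data$median_delay_s)) +
    ggplot2::geom_abline(slope = object$slope_s_per_cm,
                         intercept = object$intercept_s,
                         colour = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs)) +
    ggplot2::labs(x = "channel separation distance (cm)",
                  y = "median delay (s)", size = "pairs")
}

#' @describeIn surrogate_control histogram of pooled adjacent medians across
#'   surrogates.
#' @param object a `surrogate_ensemble`.
#' @param ... unused.
#' @method autoplot surrogate_ensemble
#' @export
autoplot.surrogate_ensemble <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$pooled_adjacent_median_s)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey60", colour = "grey30") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "pooled adjacent median delay (s)",
                  y = "surrogates")
}
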