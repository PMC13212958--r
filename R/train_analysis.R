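#' Build a spike-train tibble from onset times
#'
#' Convenience constructor for the two-column (channel, onset) form used by
#' the train and propagation functions. [detect_spikes()] output can be used
#' directly wherever a spike train is expected.
#'
#' @param onsets numeric onset times in seconds.
#' @param channel channel label.
#' @return tibble with columns `channel`, `onset_s`, sorted by onset.
#' @export
spike_train <- function(onsets, channel = "ch1") {
  stopifnot(is.numeric(onsets))
  tibble::tibble(channel = as.character(channel), onset_s = sort(onsets))
}

#' Inter-spike intervals per channel
#'
#' The interval sequence of a channel is the set of differences between
#' onset times of successive spikes on that channel.
#'
#' @param spikes tibble with `channel` and `onset_s` columns
#'   ([detect_spikes()] output or [spike_train()]).
#' @return tibble with columns `channel`, `interval_id`, `isi_s`; a channel
#'   with fewer than two spikes contributes no rows.
#' @export
#' @examples
#' compute_isis(spike_train(c(0, 100, 250)))
compute_isis <- function(spikes) {
  spikes |>
    dplyr::group_by(.data$channel) |>
    dplyr::arrange(.data$onset_s, .by_group = TRUE) |>
    dplyr::reframe(interval_id = seq_len(max(dplyr::n() - 1L, 0L)),
                   isi_s = diff(.data$onset_s))
}

#' Interval statistics: mean, median, spread, and regularity
#'
#' The coefficient of variation CV = sd/mean of the intervals distinguishes
#' near-periodic spiking (CV near 0) from Poisson-like irregularity (CV near
#' 1). `heavy_tailed` flags channels whose interval median falls below the
#' mean, the signature of a right-skewed interval distribution.
#'
#' @param isis tibble from [compute_isis()] (columns `channel`, `isi_s`).
#' @param pooled also append a `"pooled"` row computed over all intervals
#'   from all channels together.
#' @return tibble with one row per channel (plus the pooled row): `channel`,
#'   `n_intervals`, `mean_s`, `median_s`, `sd_s`, `cv`, `heavy_tailed`.
#'   An empty interval set yields a single all-`NA` row with
#'   `n_intervals = 0` rather than an error.
#' @export
isi_stats <- function(isis, pooled = TRUE) {
  one <- function(channel, x) {
    if (length(x) == 0) {
      return(tibble::tibble(channel = channel, n_intervals = 0L,
                            mean_s = NA_real_, median_s = NA_real_,
                            sd_s = NA_real_, cv = NA_real_,
                            heavy_tailed = NA))
    }
    m <- mean(x)
    s <- if (length(x) > 1) stats::sd(x) else NA_real_
    tibble::tibble(channel = channel, n_intervals = length(x), mean_s = m,
                   median_s = stats::median(x), sd_s = s,
                   cv = if (!is.na(s) && m > 0) s / m else NA_real_,
                   heavy_tailed = stats::median(x) < m)
  }
  if (nrow(isis) == 0) return(one("pooled", numeric()))
  per <- isis |>
    dplyr::group_by(.data$channel) |>
    dplyr::group_map(~ one(.y$channel, .x$isi_s)) |>
    dplyr::bind_rows()
  if (pooled) per <- dplyr::bind_rows(per, one("pooled", isis$isi_s))
  per
}

#' Detect bursts of closely spaced spikes
#'
#' A burst is a run of two or more spikes on one channel separated by
#' intervals each shorter than `fraction` (default 30%) of that channel's
#' own median inter-spike interval, computed over the full recording. Both
#' endpoints of every qualifying interval belong to the burst. A channel
#' needs at least three onsets for its median interval (and hence the
#' threshold) to be meaningful; channels with fewer contribute no bursts.
#'
#' @param spikes tibble with `channel` and `onset_s` columns.
#' @param fraction burst threshold as a fraction of the channel median ISI,
#'   in (0, 1).
#' @return tibble with one row per burst: `channel`, `burst_id`,
#'   `first_spike`, `last_spike` (positions within the channel's ordered
#'   train), `size`, `start_s`, `end_s`.
#' @export
#' @examples
#' detect_bursts(spike_train(c(0, 200, 1400, 2600)))
detect_bursts <- function(spikes, fraction = 0.30) {
  stopifnot(fraction > 0, fraction < 1)
  empty <- tibble::tibble(channel = character(), burst_id = integer(),
                          first_spike = integer(), last_spike = integer(),
                          size = integer(), start_s = numeric(),
                          end_s = numeric())
  if (nrow(spikes) == 0) return(empty)
  spikes |>
    dplyr::group_by(.data$channel) |>
    dplyr::group_map(function(df, key) {
      on <- sort(df$onset_s)
      if (length(on) < 3) return(NULL)
      isi <- diff(on)
      thr <- fraction * stats::median(isi)
      short <- isi < thr
      if (!any(short)) return(NULL)
      r <- rle(short)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      ks <- which(r$values)
      tibble::tibble(
        channel = key$channel,
        burst_id = seq_along(ks),
        first_spike = starts[ks],           # interval i joins spikes i, i+1
        last_spike = ends[ks] + 1L,
        size = ends[ks] + 1L - starts[ks] + 1L,
        start_s = on[starts[ks]],
        end_s = on[ends[ks] + 1L]
      )
    }) |>
    dplyr::bind_rows() |>
    (\(x) if (nrow(x) == 0) empty else x)()
}

#' Share of spikes occurring inside bursts
#'
#' @inheritParams detect_bursts
#' @return tibble with per-channel rows plus a `"pooled"` row: `channel`,
#'   `n_spikes`, `n_burst_spikes`, `burst_fraction`. Channels with fewer
#'   than three onsets get `burst_fraction = 0`.
#' @export
burst_stats <- function(spikes, fraction = 0.30) {
  bursts <- detect_bursts(spikes, fraction)
  per <- spikes |>
    dplyr::count(.data$channel, name = "n_spikes") |>
    dplyr::left_join(
      bursts |>
        dplyr::group_by(.data$channel) |>
        dplyr::summarise(n_burst_spikes = sum(.data$size)),
      by = "channel"
    ) |>
    dplyr::mutate(
      n_burst_spikes = dplyr::coalesce(.data$n_burst_spikes, 0L),
      burst_fraction = .data$n_burst_spikes / .data$n_spikes
    )
  pooled <- tibble::tibble(
    channel = "pooled",
    n_spikes = sum(per$n_spikes),
    n_burst_spikes = sum(per$n_burst_spikes),
    burst_fraction = sum(per$n_burst_spikes) / max(sum(per$n_spikes), 1L)
  )
  dplyr::bind_rows(per, pooled)
}

#' Restrict spike trains to a time window
#'
#' Returns the per-channel onset lists inside `[t0, t1]`, the form used for
#' raster displays; channel labels and ordering are preserved, and channels
#' with no onsets in the window are kept with zero rows.
#'
#' @param spikes tibble with `channel` and `onset_s` columns.
#' @param t0,t1 window bounds in seconds, `t0 < t1`.
#' @return tibble with columns `channel`, `onset_s` restricted to the window.
#' @export
raster_data <- function(spikes, t0, t1) {
  stopifnot(t0 < t1)
  spikes |>
    dplyr::filter(.data$onset_s >= t0, .data$onset_s <= t1) |>
    dplyr::select("channel", "onset_s") |>
    dplyr::arrange(.data$channel, .data$onset_s)
}
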