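#' Detect slow supra-threshold spikes
#'
#' A spike on a channel is a maximal run of consecutive samples whose
#' potential exceeds `baseline + k * sigma`, where the baseline is the
#' channel median and sigma its full-series standard deviation (see
#' [channel_stats()]). A run is kept only if it lasts at least `w_min`
#' seconds; there is no upper duration limit. Onset is the time of the first
#' supra-threshold sample, termination the last, width is the number of
#' supra-threshold samples times the sampling interval (so a 60-sample run at
#' 1 Hz has width exactly 60 s), and amplitude is the maximum deviation from
#' baseline within the run.
#'
#' A sampling gap (successive times more than 1.5 x the sampling interval
#' apart) terminates any open run: contiguity is defined on consecutive time
#' steps, and no value is ever interpolated across a gap.
#'
#' @param rec a `recording`.
#' @param k threshold multiplier on sigma (default 2.0).
#' @param w_min minimum spike duration in seconds (default 60).
#' @param channels channels to scan; default all.
#' @param polarity `"positive"` detects excursions above
#'   `baseline + k * sigma` (the default, and the definition used throughout);
#'   `"negative"` mirrors the rule below `baseline - k * sigma`.
#'
#' @return tibble with one row per spike: `channel`, `onset_s`,
#'   `termination_s`, `width_s`, `amplitude_mV`, `peak_time_s`, `n_samples`,
#'   ordered by channel then onset. Attributes `k`, `w_min` record the
#'   parameters used.
#' @export
#' @examples
#' tr <- c(rep(0, 50), rep(0.5, 120), rep(0, 50))
#' rec <- as_recording(data.frame(time_s = seq_along(tr) - 1,
#'                                a = tr + rnorm(220, sd = 0.01),
#'                                b = rnorm(220, sd = 0.01)))
#' detect_spikes(rec, k = 2, w_min = 60)
detect_spikes <- function(rec, k = 2.0, w_min = 60, channels = NULL,
                          polarity = c("positive", "negative")) {
  stopifnot(k > 0, w_min > 0)
  polarity <- match.arg(polarity)
  labs <- resolve_channels(rec, channels)
  t <- rec$time_s
  dt <- sampling_interval(rec)

  out <- purrr::map_dfr(labs, function(ch) {
    v <- rec[[ch]]
    baseline <- stats::median(v, na.rm = TRUE)
    sigma <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(sigma) || sigma == 0) {
      stop("channel '", ch, "': zero-variance series, threshold undefined",
           call. = FALSE)
    }
    if (polarity == "negative") {
      above <- !is.na(v) & (v < baseline - k * sigma)
      dev <- baseline - v
    } else {
      above <- !is.na(v) & (v > baseline + k * sigma)
      dev <- v - baseline
    }
    i <- which(above)
    if (length(i) == 0) return(empty_spike_tbl())

    # split supra-threshold samples into contiguous runs; a time gap breaks a run
    new_run <- c(TRUE, diff(i) != 1L | diff(t[i]) > 1.5 * dt)
    start_pos <- which(new_run)
    end_pos <- c(start_pos[-1] - 1L, length(i))
    n_run <- end_pos - start_pos + 1L
    keep <- which(n_run * dt >= w_min)
    if (length(keep) == 0) return(empty_spike_tbl())

    peak_idx <- vapply(keep, function(r) {
      idx <- i[start_pos[r]:end_pos[r]]
      idx[which.max(dev[idx])]
    }, integer(1))
    tibble::tibble(
      channel = ch,
      onset_s = t[i[start_pos[keep]]],
      termination_s = t[i[end_pos[keep]]],
      width_s = n_run[keep] * dt,
      amplitude_mV = dev[peak_idx],
      peak_time_s = t[peak_idx],
      n_samples = n_run[keep]
    )
  })
  out <- dplyr::arrange(out, .data$channel, .data$onset_s)
  attr(out, "k") <- k
  attr(out, "w_min") <- w_min
  out
}

empty_spike_tbl <- function() {
  tibble::tibble(channel = character(), onset_s = numeric(),
                 termination_s = numeric(), width_s = numeric(),
                 amplitude_mV = numeric(), peak_time_s = numeric(),
                 n_samples = integer())
}

#' Summarise spike width and amplitude distributions
#'
#' Width and amplitude distributions in these recordings are strongly
#' right-skewed, so medians are reported alongside means.
#'
#' @param spikes spike tibble from [detect_spikes()].
#' @return tibble with one row per metric (`width_s`, `amplitude_mV`):
#'   `n`, `mean`, `median`, `sd`, `q25`, `q75`, `iqr`. With no spikes the
#'   rows are retained with `n = 0` and `NA` statistics.
#' @export
summarize_spikes <- function(spikes) {
  one <- function(metric, x) {
    if (length(x) == 0) {
      return(tibble::tibble(metric = metric, n = 0L, mean = NA_real_,
                            median = NA_real_, sd = NA_real_, q25 = NA_real_,
                            q75 = NA_real_, iqr = NA_real_))
    }
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
    tibble::tibble(metric = metric, n = length(x), mean = mean(x),
                   median = stats::median(x),
                   sd = if (length(x) > 1) stats::sd(x) else NA_real_,
                   q25 = q[1], q75 = q[2], iqr = q[2] - q[1])
  }
  dplyr::bind_rows(one("width_s", spikes$width_s),
                   one("amplitude_mV", spikes$amplitude_mV))
}

#' Onset-aligned, peak-normalised average spike shape
#'
#' Each spike's segment from `pre` seconds before onset to `post` seconds
#' after is extracted, the channel baseline subtracted, and the result
#' divided by that spike's amplitude, so every contributing waveform has
#' maximum 1 inside the spike. The pointwise mean and 25th/75th percentiles
#' across events are returned on the common grid. Events whose window runs
#' off either edge of the recording are dropped and counted in the
#' `n_dropped` attribute.
#'
#' @param rec the `recording` the spikes were detected in.
#' @param spikes spike tibble from [detect_spikes()]; must be non-empty.
#' @param pre,post window extent before and after onset, seconds. The
#'   default (-60 s, +1200 s) covers the typical width range of slow fungal
#'   spikes (roughly 1e2 to 1.2e3 s).
#' @return tibble of class `spike_shape` with columns `time_s` (relative to
#'   onset), `mean`, `q25`, `q75`; attributes `n_events`, `n_dropped`.
#' @export
average_spike_shape <- function(rec, spikes, pre = 60, post = 1200) {
  stopifnot(pre >= 0, post > 0)
  if (nrow(spikes) == 0) stop("no spikes to average", call. = FALSE)
  dt <- sampling_interval(rec)
  t <- rec$time_s
  grid <- seq(-pre, post, by = dt)
  stats_tbl <- channel_stats(rec)
  baselines <- stats::setNames(stats_tbl$baseline_mV, stats_tbl$channel)

  segs <- purrr::pmap(
    list(spikes$channel, spikes$onset_s, spikes$amplitude_mV),
    function(ch, onset, amp) {
      want <- onset + grid
      if (want[1] < t[1] - dt / 2 || want[length(want)] > t[length(t)] + dt / 2) {
        return(NULL)  # edge-truncated
      }
      idx <- round((want - t[1]) / dt) + 1L
      if (any(idx < 1L | idx > length(t))) return(NULL)
      (rec[[ch]][idx] - baselines[[ch]]) / amp
    }
  )
  keep <- !vapply(segs, is.null, logical(1))
  if (!any(keep)) stop("all events are edge-truncated", call. = FALSE)
  m <- do.call(rbind, segs[keep])

  out <- tibble::tibble(
    time_s = grid,
    mean = colMeans(m),
    q25 = apply(m, 2, stats::quantile, probs = 0.25, names = FALSE),
    q75 = apply(m, 2, stats::quantile, probs = 0.75, names = FALSE)
  )
  class(out) <- c("spike_shape", class(out))
  attr(out, "n_events") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}
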