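#' Run the full spike-propagation analysis pipeline
#'
#' Executes every stage in order on one recording: per-channel baseline and
#' sigma, spike detection, width/amplitude summaries, onset-aligned average
#' spike shape, inter-spike-interval and burst statistics, the lead-lag
#' delay matrix, delay versus separation, the robust velocity fit, the
#' permutation surrogate control, and the threshold sensitivity analysis.
#' The pipeline is deterministic given the recording, the parameters, and
#' `seed` (which governs only the surrogate randomisation).
#'
#' @param rec a `recording`.
#' @param k threshold multiplier (default 2.0).
#' @param w_min minimum spike duration in seconds (default 60).
#' @param dt_max base association window in seconds (default 300).
#' @param window_policy,matching see [association_params()].
#' @param burst_fraction burst threshold as a fraction of the channel median
#'   ISI (default 0.30).
#' @param n_surrogates surrogate count (default 100).
#' @param k_sensitivity extra thresholds for the sensitivity analysis; `k`
#'   itself is always included.
#' @param shape_window `c(pre, post)` seconds for the average spike shape.
#' @param seed integer seed for the surrogate control.
#' @param outdir if non-`NULL`, all tables are written there as
#'   tab-delimited text via [write_report()].
#' @return object of class `analysis_report`: a named list of tibbles and
#'   fitted objects (`channel_stats`, `spikes`, `spike_summary`,
#'   `spike_shape`, `isis`, `isi_summary`, `bursts`, `burst_summary`,
#'   `delay_matrix`, `separation_delays`, `velocity`, `surrogates`,
#'   `surrogate_summary`, `sensitivity`, `provenance`).
#' @export
run_pipeline <- function(rec, k = 2.0, w_min = 60, dt_max = 300,
                         window_policy = c("scaled", "fixed"),
                         matching = c("one_to_one_nearest", "all_pairs"),
                         burst_fraction = 0.30, n_surrogates = 100,
                         k_sensitivity = c(1.5, 2.5),
                         shape_window = c(60, 1200), seed = 1L,
                         outdir = NULL) {
  window_policy <- match.arg(window_policy)
  matching <- match.arg(matching)
  if (n_channels(rec) < 2) stop("need at least 2 channels", call. = FALSE)
  params <- association_params(dt_max, window_policy, matching)
  labs <- channel_labels(rec)

  stats_tbl <- channel_stats(rec)
  spikes <- detect_spikes(rec, k = k, w_min = w_min)
  spike_summary <- summarize_spikes(spikes)
  shape <- if (nrow(spikes) > 0) {
    tryCatch(average_spike_shape(rec, spikes, pre = shape_window[1],
                                 post = shape_window[2]),
             error = function(e) NULL)
  }
  isis <- compute_isis(spikes)
  isi_summary <- isi_stats(isis)
  bursts <- detect_bursts(spikes, fraction = burst_fraction)
  burst_summary <- burst_stats(spikes, fraction = burst_fraction)

  dm <- lead_lag_matrix(spikes, params, channels = labs)
  sep <- delay_vs_separation(dm, spacing_cm = spacing_cm(rec))
  vel <- tryCatch(fit_velocity(sep), error = function(e) NULL)

  surr <- surrogate_control(spikes, duration = recording_duration(rec),
                            n_surrogates = n_surrogates, params = params,
                            channels = labs, seed = seed)
  sens <- threshold_sensitivity(rec, k_values = sort(unique(c(k, k_sensitivity))),
                                w_min = w_min, params = params)

  report <- structure(list(
    channel_stats = stats_tbl,
    spikes = spikes,
    spike_summary = spike_summary,
    spike_shape = shape,
    isis = isis,
    isi_summary = isi_summary,
    bursts = bursts,
    burst_summary = burst_summary,
    delay_matrix = dm,
    separation_delays = sep,
    velocity = vel,
    surrogates = surr,
    surrogate_summary = glance(surr),
    sensitivity = sens,
    provenance = list(
      k = k, w_min = w_min, dt_max = dt_max,
      window_policy = window_policy, matching = matching,
      burst_fraction = burst_fraction, n_surrogates = n_surrogates,
      k_sensitivity = k_sensitivity, seed = seed,
      spacing_cm = spacing_cm(rec),
      sampling_interval_s = sampling_interval(rec),
      n_channels = n_channels(rec), n_samples = nrow(rec),
      duration_s = recording_duration(rec),
      input_digest = recording_digest(rec),
      package_version = as.character(utils::packageVersion("mycospike"))
    )
  ), class = "analysis_report")

  if (!is.null(outdir)) write_report(report, outdir)
  report
}

# order-sensitive checksum of the numeric content; enough to recognise an
# identical rerun without a cryptographic digest dependency
recording_digest <- function(rec) {
  m <- as.matrix(tibble::as_tibble(rec))
  sprintf("n%d-s%.10e-w%.10e", length(m), sum(m),
          sum(m * seq_along(m) %% 97))
}

#' @export
print.analysis_report <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("<analysis_report> %d channels, %.3g s, k = %g, w_min = %g s\n",
              p$n_channels, p$duration_s, p$k, p$w_min))
  cat(sprintf("  spikes: %d (median width %.0f s, median amplitude %.2f mV)\n",
              nrow(x$spikes),
              x$spike_summary$median[x$spike_summary$metric == "width_s"],
              x$spike_summary$median[x$spike_summary$metric == "amplitude_mV"]))
  pooled <- x$isi_summary[x$isi_summary$channel == "pooled", ]
  if (nrow(pooled) == 1 && pooled$n_intervals > 0) {
    cat(sprintf("  ISI: median %.3g s, CV %.2f; burst fraction %.2f\n",
                pooled$median_s, pooled$cv,
                x$burst_summary$burst_fraction[
                  x$burst_summary$channel == "pooled"]))
  }
  adj <- x$delay_matrix$pairs$delay_s[x$delay_matrix$pairs$separation == 1]
  if (length(adj)) {
    cat(sprintf("  adjacent median delay: %.1f s over %d pairs\n",
                stats::median(adj), length(adj)))
  }
  if (!is.null(x$velocity)) {
    cat(sprintf("  velocity: %.3f cm/min (%.1f cm/h), %s fit\n",
                x$velocity$velocity_cm_per_min, x$velocity$velocity_cm_per_h,
                x$velocity$method))
  }
  ss <- x$surrogate_summary
  cat(sprintf("  surrogates: %d, pooled adjacent median %.1f s, monotone fraction %.2f\n",
              ss$n_surrogates, ss$pooled_adjacent_median_s,
              ss$monotone_fraction))
  invisible(x)
}

#' Write all report tables to a directory
#'
#' Tab-delimited text per stage plus a `summary.json` (when jsonlite is
#' available) holding the headline numbers and the provenance block.
#'
#' @param report an `analysis_report`.
#' @param outdir output directory, created if needed.
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    readr::write_tsv(df, file.path(outdir, paste0(name, ".tsv")),
                     progress = FALSE)
  }
  w(report$channel_stats, "channel_stats")
  w(report$spikes, "spikes")
  w(report$spike_summary, "spike_summary")
  if (!is.null(report$spike_shape)) {
    w(tibble::as_tibble(report$spike_shape), "spike_shape")
  }
  w(report$isis, "isis")
  w(report$isi_summary, "isi_summary")
  w(report$bursts, "bursts")
  w(report$burst_summary, "burst_summary")
  w(tidy(report$delay_matrix), "delay_matrix")
  w(report$separation_delays, "separation_delays")
  if (!is.null(report$velocity)) {
    w(glance(report$velocity), "velocity")
    w(report$velocity$per_separation, "per_separation_velocity")
  }
  w(dplyr::select(report$surrogates, -"matrix"), "surrogates")
  w(report$surrogate_summary, "surrogate_summary")
  w(report$sensitivity, "sensitivity")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    head <- list(
      provenance = report$provenance,
      median_width_s =
        report$spike_summary$median[report$spike_summary$metric == "width_s"],
      median_amplitude_mV =
        report$spike_summary$median[
          report$spike_summary$metric == "amplitude_mV"],
      velocity_cm_per_min =
        if (!is.null(report$velocity)) report$velocity$velocity_cm_per_min,
      surrogate_summary = as.list(report$surrogate_summary)
    )
    jsonlite::write_json(head, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(outdir)
}
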