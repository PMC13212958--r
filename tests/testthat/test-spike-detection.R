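test_that("a rectangular plateau is detected with its width and amplitude", {
  set.seed(1)
  v <- plateau_trace(n_total = 400, start = 101, len = 120, height = 0.5)
  rec <- make_recording(a = v, b = rnorm(400, sd = 0.01))
  sp <- detect_spikes(rec, k = 2, w_min = 60, channels = "a")
  expect_equal(nrow(sp), 1)
  expect_equal(sp$onset_s, 100)
  expect_equal(sp$width_s, 120)
  expect_equal(sp$termination_s, 219)
  expect_equal(sp$amplitude_mV, 0.5, tolerance = 0.15)
})

test_that("the minimum-duration rule is sharp at w_min samples", {
  set.seed(2)
  mk <- function(len) {
    make_recording(a = plateau_trace(400, start = 101, len = len),
                   b = rnorm(400, sd = 0.01))
  }
  expect_equal(nrow(detect_spikes(mk(59), channels = "a")), 0)
  sp <- detect_spikes(mk(60), channels = "a")
  expect_equal(nrow(sp), 1)
  expect_equal(sp$width_s, 60)
})

test_that("a trace never exceeding threshold yields an empty table", {
  set.seed(3)
  rec <- make_recording(a = rnorm(500, sd = 0.05), b = rnorm(500, sd = 0.05))
  # pure noise can still cross 2 sigma briefly, but never for 60 s
  expect_equal(nrow(detect_spikes(rec, k = 2, w_min = 60)), 0)
})

test_that("zero-variance channel raises a threshold-undefined error", {
  rec <- make_recording(a = rep(1, 100), b = rnorm(100))
  expect_error(detect_spikes(rec, channels = "a"), "threshold undefined")
})

test_that("detection matches the brute-force scanner on random traces", {
  set.seed(20)
  for (r in 1:25) {
    v <- random_event_trace(n = 1000)
    rec <- make_recording(a = v, b = rnorm(1000, sd = 0.01))
    sp <- detect_spikes(rec, k = 2, w_min = 60, channels = "a")
    or <- oracle_scan_spikes(v, 0:999, k = 2, w_min = 60)
    expect_equal(sp$onset_s, or$onset_s)
    expect_equal(sp$termination_s, or$termination_s)
    expect_equal(sp$width_s, or$width_s)
    expect_equal(sp$amplitude_mV, or$amplitude_mV)
  }
})

test_that("event count is monotone non-increasing in the threshold k", {
  set.seed(21)
  for (r in 1:10) {
    rec <- make_recording(a = random_event_trace(2000, n_events = 6),
                          b = random_event_trace(2000, n_events = 6))
    counts <- vapply(c(1.5, 2.0, 2.5),
                     function(k) nrow(detect_spikes(rec, k = k)), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("widths respect w_min and events never overlap within a channel", {
  set.seed(22)
  rec <- make_recording(a = random_event_trace(3000, n_events = 10),
                        b = random_event_trace(3000, n_events = 10))
  sp <- detect_spikes(rec, k = 1.5, w_min = 60)
  expect_true(all(sp$width_s >= 60))
  for (ch in unique(sp$channel)) {
    s <- sp[sp$channel == ch, ]
    if (nrow(s) > 1) {
      expect_true(all(s$onset_s[-1] > s$termination_s[-nrow(s)]))
    }
  }
})

test_that("a sampling gap acts as a segment boundary and never merges runs", {
  set.seed(23)
  # supra-threshold plateau spanning a 10 s hole in the time grid
  t <- c(0:199, 210:409)
  v <- rnorm(400, sd = 0.01)
  v[121:280] <- v[121:280] + 1   # samples at t in [120,199] and [210,289]
  rec <- as_recording(tibble::tibble(time_s = t, a = v, b = rnorm(400, sd = 0.01)),
                      sampling_interval = 1)
  sp <- detect_spikes(rec, k = 1.5, w_min = 60, channels = "a")
  expect_equal(nrow(sp), 2)
  expect_lte(sp$termination_s[1], 199)
  expect_gte(sp$onset_s[2], 210)
})

test_that("spike summaries report medians alongside means", {
  sp <- tibble::tibble(width_s = c(100, 200, 300),
                       amplitude_mV = c(0.2, 0.6, 1.0))
  sm <- summarize_spikes(sp)
  expect_equal(sm$median[sm$metric == "width_s"], 200)
  expect_equal(sm$mean[sm$metric == "width_s"], 200)
  expect_equal(sm$q25[sm$metric == "amplitude_mV"], 0.4)

  empty <- summarize_spikes(empty_tbl <- detect_spikes(
    make_recording(a = rnorm(100, sd = 0.01), b = rnorm(100, sd = 0.01))))
  expect_equal(empty$n, c(0L, 0L))
  expect_true(all(is.na(empty$median)))
})

test_that("identical spikes give a zero-dispersion average shape peaking at 1", {
  set.seed(30)
  v <- rep(0, 3000)
  onsets <- c(500, 1500, 2500)
  wave <- spike_kernel(0:299, 40, 120)
  for (o in onsets) v[o + 1 + 0:299] <- v[o + 1 + 0:299] + 0.8 * wave
  rec <- make_recording(a = v + rnorm(3000, sd = 1e-4),
                        b = rnorm(3000, sd = 1e-4))
  sp <- detect_spikes(rec, k = 2, w_min = 60, channels = "a")
  expect_equal(nrow(sp), 3)
  sh <- average_spike_shape(rec, sp, pre = 60, post = 400)
  expect_equal(sh$q25, sh$q75, tolerance = 1e-2)
  expect_equal(max(sh$mean), 1, tolerance = 1e-2)
  expect_equal(attr(sh, "n_events"), 3)
})

test_that("a single spike's average shape is its own normalised waveform", {
  v <- rep(0, 1200)
  v[301:700] <- spike_kernel(0:399, 60, 240) * 0.9
  rec <- make_recording(a = v + rnorm(1200, sd = 1e-4),
                        b = rnorm(1200, sd = 1e-4))
  sp <- detect_spikes(rec, channels = "a")
  sh <- average_spike_shape(rec, sp, pre = 50, post = 500)
  expect_equal(attr(sh, "n_events"), 1)
  expect_equal(max(sh$mean), 1, tolerance = 1e-2)
  expect_equal(sh$mean, sh$q75)
})

test_that("asymmetric kernels give onset-to-peak shorter than peak-to-half-decay", {
  set.seed(31)
  cfg <- synthetic_config(n_channels = 2, duration_s = 6e4, seed = 31,
                          isi_median_s = 3e3, noise_sd_mV = 0.02,
                          lag_jitter_sd = 0, burst_prob = 0)
  sim <- simulate_recording(cfg)
  sp <- detect_spikes(sim$recording)
  sh <- average_spike_shape(sim$recording, sp, pre = 60, post = 1200)
  peak_i <- which.max(sh$mean)
  onset_i <- which(sh$time_s == 0)
  after <- sh$mean[peak_i:nrow(sh)]
  half_i <- peak_i + which(after <= max(sh$mean) / 2)[1] - 1
  rise_time <- sh$time_s[peak_i] - sh$time_s[onset_i]
  decay_half_time <- sh$time_s[half_i] - sh$time_s[peak_i]
  expect_lt(rise_time, decay_half_time)
})

test_that("edge-truncated events are dropped and counted; all-truncated errors", {
  v <- rep(0, 1000)
  v[11:200] <- 0.8    # onset at t = 10 < pre window
  v[501:660] <- 0.8
  rec <- make_recording(a = v + rnorm(1000, sd = 1e-3),
                        b = rnorm(1000, sd = 1e-3))
  sp <- detect_spikes(rec, channels = "a")
  expect_equal(nrow(sp), 2)
  sh <- average_spike_shape(rec, sp, pre = 60, post = 150)
  expect_equal(attr(sh, "n_dropped"), 1)
  expect_error(average_spike_shape(rec, sp, pre = 60, post = 1200),
               "edge-truncated")
})

test_that("negative polarity mirrors the detection rule", {
  set.seed(33)
  v <- -plateau_trace(400, start = 101, len = 100, height = 0.6)
  rec <- make_recording(a = v, b = rnorm(400, sd = 0.01))
  expect_equal(nrow(detect_spikes(rec, channels = "a")), 0)
  sp <- detect_spikes(rec, channels = "a", polarity = "negative")
  expect_equal(nrow(sp), 1)
  expect_gt(sp$amplitude_mV, 0)
})
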