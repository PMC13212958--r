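test_that("association respects the window and the greedy tie rule", {
  p <- association_params(dt_max = 300, window_policy = "fixed")
  expect_equal(nrow(associate_spike_pairs(0, 400, p)), 0)

  one <- associate_spike_pairs(0, 120, p)
  expect_equal(one$delay_s, 120)

  # two lead candidates for one lag spike: nearest wins, each spike used once
  tie <- associate_spike_pairs(c(0, 10), 5, p)
  expect_equal(nrow(tie), 1)
  expect_equal(tie$lead_onset_s, 0)   # |5| == |-5|: smaller lead onset first
  expect_equal(tie$delay_s, 5)

  ap <- associate_spike_pairs(c(0, 10), 5,
                              association_params(matching = "all_pairs"))
  expect_equal(nrow(ap), 2)
})

test_that("one-to-one matching negates delays exactly when lead/lag swap", {
  set.seed(40)
  for (r in 1:10) {
    a <- sort(runif(30, 0, 1e4))
    b <- sort(runif(30, 0, 1e4))
    p <- association_params(dt_max = 300)
    fwd <- associate_spike_pairs(a, b, p)
    rev <- associate_spike_pairs(b, a, p)
    expect_equal(sort(rev$delay_s), sort(-fwd$delay_s))
  }
})

test_that("no reported delay exceeds the effective window", {
  set.seed(41)
  p_fixed <- association_params(dt_max = 200, window_policy = "fixed")
  p_scaled <- association_params(dt_max = 200, window_policy = "scaled")
  a <- sort(runif(50, 0, 2e4)); b <- sort(runif(50, 0, 2e4))
  expect_true(all(abs(associate_spike_pairs(a, b, p_fixed, 3)$delay_s) <= 200))
  expect_true(all(abs(associate_spike_pairs(a, b, p_scaled, 3)$delay_s) <= 600))
})

test_that("delay distributions summarise signed delays", {
  expect_equal(delay_distribution(tibble::tibble(delay_s = c(10, 20, 30)))$median_s, 20)
  expect_equal(delay_distribution(tibble::tibble(delay_s = c(-50, 50)))$median_s, 0)
  expect_equal(delay_distribution(tibble::tibble(delay_s = numeric()))$n, 0)
})

test_that("identical trains give an all-zero defined lead-lag matrix", {
  sp <- shifted_trains(lag = 0)
  dm <- lead_lag_matrix(sp)
  defined <- !is.na(dm$median_delay)
  expect_true(all(defined))
  expect_true(all(dm$median_delay == 0))
})

test_that("trains shifted by 60 s per channel give entries 60 x (d - c)", {
  sp <- shifted_trains(lag = 60, n_channels = 4)
  dm <- lead_lag_matrix(sp, association_params(window_policy = "scaled"))
  C <- 4
  for (c in 1:C) for (d in 1:C) {
    expect_equal(dm$median_delay[c, d], 60 * (d - c))
  }
  expect_true(lead_lag_monotone(dm))
})

test_that("the lead-lag matrix is antisymmetric and shift invariant", {
  set.seed(42)
  sp <- purrr::map_dfr(1:4, function(c) {
    tibble::tibble(channel = sprintf("ch%d", c),
                   onset_s = sort(runif(25, 0, 5e4)))
  })
  dm <- lead_lag_matrix(sp)
  expect_equal(dm$median_delay, -t(dm$median_delay))
  sp2 <- dplyr::mutate(sp, onset_s = onset_s + 777)
  dm2 <- lead_lag_matrix(sp2)
  expect_equal(dm2$median_delay, dm$median_delay)
  expect_equal(dm2$pair_count, dm$pair_count)
})

test_that("delay-vs-separation pools pairs and converts to distance", {
  sp <- shifted_trains(lag = 100, n_channels = 3)
  dm <- lead_lag_matrix(sp, association_params(window_policy = "scaled"))
  sep <- delay_vs_separation(dm, spacing_cm = 2)
  expect_equal(sep$separation, 1:2)
  expect_equal(sep$distance_cm, c(2, 4))
  expect_equal(sep$median_delay_s, c(100, 200))
  expect_equal(sep$n_pairs, c(8L, 4L))
})

test_that("separations with no pairs are reported with zero counts", {
  # two sparse far channels plus an empty one: separation 2 has no pairs
  sp <- dplyr::bind_rows(spike_train(c(100, 5000), "ch1"),
                         spike_train(c(150, 5050), "ch2"))
  dm <- lead_lag_matrix(sp, channels = c("ch1", "ch2", "ch3"))
  sep <- delay_vs_separation(dm)
  expect_equal(sep$n_pairs[sep$separation == 2], 0L)
  expect_true(is.na(sep$median_delay_s[sep$separation == 2]))
})

test_that("an exact line is fit exactly and velocities follow closed form", {
  sep <- tibble::tibble(separation = 1:7, distance_cm = 2 * (1:7),
                        median_delay_s = 90 * (1:7), n_pairs = 10L)
  fit <- fit_velocity(sep)
  expect_equal(fit$slope_s_per_cm, 45)
  expect_equal(fit$intercept_s, 0)
  expect_equal(fit$velocity_cm_per_min, 60 / 45)
  expect_equal(fit$velocity_cm_per_h, 60 * 60 / 45)
  expect_equal(fit$per_separation$velocity_cm_per_min,
               rep(60 * 2 / 90, 7))
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "slope_s_per_cm"], 45)
  expect_equal(glance(fit)$method, "Theil-Sen")
})

test_that("constant delays give zero slope and undefined velocity", {
  sep <- tibble::tibble(separation = 1:4, distance_cm = 2 * (1:4),
                        median_delay_s = rep(120, 4), n_pairs = 5L)
  fit <- fit_velocity(sep)
  expect_equal(fit$slope_s_per_cm, 0)
  expect_true(is.na(fit$velocity_cm_per_min))
})

test_that("adjacent-channel arithmetic gives the expected velocities", {
  v <- velocity_from_adjacent(60, 2)
  expect_equal(v$velocity_cm_per_min, 2)
  expect_equal(velocity_from_adjacent(120, 4)$velocity_cm_per_min, 2)
  expect_error(velocity_from_adjacent(0), "positive")
  expect_error(velocity_from_adjacent(-10), "positive")
})

test_that("surrogates preserve counts and are reproducible under a seed", {
  set.seed(43)
  sp <- purrr::map_dfr(1:4, function(c) {
    tibble::tibble(channel = sprintf("ch%d", c),
                   onset_s = sort(runif(20, 0, 5e4)))
  })
  ens1 <- surrogate_control(sp, duration = 5e4, n_surrogates = 5, seed = 99)
  ens2 <- surrogate_control(sp, duration = 5e4, n_surrogates = 5, seed = 99)
  expect_identical(ens1$pooled_adjacent_median_s, ens2$pooled_adjacent_median_s)
  expect_identical(ens1$monotone, ens2$monotone)

  orig <- vapply(sort(unique(sp$channel)),
                 function(ch) sum(sp$channel == ch), integer(1))
  for (cts in ens1$counts) expect_equal(unname(cts), unname(orig))

  ens3 <- surrogate_control(sp, duration = 5e4, n_surrogates = 3,
                            mode = "isi_shuffle", seed = 1)
  for (cts in ens3$counts) expect_equal(unname(cts), unname(orig))
})

test_that("surrogate randomisation collapses genuine propagation structure", {
  set.seed(44)
  sp <- shifted_trains(base = sort(runif(40, 2000, 1.8e5)), lag = 170,
                       n_channels = 8)
  dm <- lead_lag_matrix(sp)
  expect_true(lead_lag_monotone(dm))
  ens <- surrogate_control(sp, duration = 2e5, n_surrogates = 50, seed = 7)
  gl <- glance(ens)
  expect_lt(abs(gl$pooled_adjacent_median_s), 30)
  expect_lte(gl$monotone_fraction, 0.05)
})

test_that("threshold sensitivity reruns the pipeline per k on a fixture", {
  sim <- shared_sim()
  sens <- threshold_sensitivity(sim$recording, k_values = c(1.5, 2.0, 2.5))
  expect_equal(sens$k, c(1.5, 2.0, 2.5))
  expect_true(all(diff(sens$n_spikes) <= 0))
  expect_true(all(sens$adjacent_positive))
  one <- threshold_sensitivity(sim$recording, k_values = 2.0)
  expect_equal(nrow(one), 1)
})
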