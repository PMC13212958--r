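# Build a recording from per-channel vectors at 1 Hz.
make_recording <- function(..., dt = 1, spacing_cm = 2) {
  cols <- list(...)
  n <- length(cols[[1]])
  as_recording(tibble::tibble(time_s = (seq_len(n) - 1) * dt, !!!cols),
               sampling_interval = dt, spacing_cm = spacing_cm)
}

# Rectangular plateau of given height/length embedded in low-level noise so
# that sigma is well defined but small.
plateau_trace <- function(n_total = 400, start = 100, len = 120,
                          height = 0.5, noise_sd = 0.01) {
  v <- rnorm(n_total, sd = noise_sd)
  v[start:(start + len - 1)] <- v[start:(start + len - 1)] + height
  v
}

# Small deterministic propagating fixture shared by propagation tests:
# identical trains shifted by `lag` per channel step.
shifted_trains <- function(base = c(1000, 5000, 9000, 15000), lag = 60,
                           n_channels = 4) {
  purrr::map_dfr(seq_len(n_channels), function(c) {
    tibble::tibble(channel = sprintf("ch%d", c),
                   onset_s = base + (c - 1) * lag)
  })
}

# One small synthetic recording reused across expensive tests (lazy, cached).
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_recording(synthetic_config(duration_s = 2e5,
                                                    seed = 42))
    }
    cache
  }
})
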