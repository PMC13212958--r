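# Independent brute-force oracles, deliberately written as plain loops with
# no shared code with the package internals.

# Scan a single trace sample by sample and collect maximal supra-threshold
# runs of at least w_min seconds. Returns a data.frame in onset order.
oracle_scan_spikes <- function(v, t, k, w_min, dt = 1) {
  baseline <- median(v)
  sigma <- sd(v)
  thr <- baseline + k * sigma
  out <- data.frame(onset_s = numeric(), termination_s = numeric(),
                    width_s = numeric(), amplitude_mV = numeric())
  run <- integer()
  flush <- function(run, out) {
    if (length(run) * dt >= w_min) {
      out[nrow(out) + 1L, ] <- c(t[run[1]], t[run[length(run)]],
                                 length(run) * dt, max(v[run]) - baseline)
    }
    out
  }
  for (s in seq_along(v)) {
    inside <- v[s] > thr
    contiguous <- length(run) == 0 || (s - run[length(run)] == 1 &&
                                         t[s] - t[run[length(run)]] <= 1.5 * dt)
    if (inside && contiguous) {
      run <- c(run, s)
    } else {
      out <- flush(run, out)
      run <- if (inside) s else integer()
    }
  }
  flush(run, out)
}

# Sort-based median and two-pass sample variance.
oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}
oracle_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# A random trace with a few injected plateaus so the detection oracle is
# exercised on both sub- and supra-threshold structure.
random_event_trace <- function(n = 1000, n_events = 3) {
  v <- rnorm(n, sd = 0.1)
  for (e in seq_len(n_events)) {
    len <- sample(20:150, 1)
    start <- sample(seq_len(n - len), 1)
    v[start:(start + len - 1)] <- v[start:(start + len - 1)] +
      runif(1, 0.3, 1.5)
  }
  v
}
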