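# Independent oracles used across the suite.

# Naive two-pass polarity index: find the max, then count portions at or
# above half of it. Deliberately written as an explicit loop, independent
# of compute_bpi().
naive_bpi <- function(v) {
  m <- v[1]
  for (x in v) if (x > m) m <- x
  k <- 0L
  for (x in v) if (x >= m / 2) k <- k + 1L
  k / length(v)
}

# Expected amplifying rounds under the truncated geometric law, by explicit
# probability-mass summation (independent of expected_si()).
e_rounds_bruteforce <- function(p_amp, max_rounds) {
  if (!is.finite(max_rounds)) max_rounds <- 10000L
  e <- 0
  for (k in seq_len(max_rounds - 1)) {
    e <- e + k * p_amp^k * (1 - p_amp)
  }
  e + max_rounds * p_amp^max_rounds
}

# Noise-free model profile evaluated at the portion midpoints.
model_profile_values <- function(baseline, amplitude, center, sigma,
                                 n = 63L) {
  th <- portion_midpoints(n)
  baseline + amplitude * wrapped_gaussian(angle_diff_oracle(th, center),
                                          sigma)
}

# Local angle difference (kept here so the oracle does not depend on
# unexported package internals).
angle_diff_oracle <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

# Disk label mask of radius r centred in an n x n image.
disk_mask <- function(n = 64L, r = 20, id = 1L) {
  c0 <- (n - 1) / 2
  xs <- 0:(n - 1)
  d2 <- outer(xs, xs, function(y, x) (x - c0)^2 + (y - c0)^2)
  m <- matrix(0L, n, n)
  m[d2 <= r^2] <- id
  m
}

# Bare peak-fit object for metric tests.
peak_fit_for_test <- function(b = 0, A = 0, mu = 0, sigma = 0.3, rmse = 0,
                              converged = TRUE) {
  structure(list(b = b, A = A, mu = mu, sigma = sigma, rmse = rmse,
                 converged = converged, degenerate = FALSE),
            class = "peak_fit")
}

# Persistence result constructed directly from a known persistence time.
persistence_result_for_test <- function(cell_id, minutes, censored = FALSE) {
  structure(list(cell_id = cell_id, persistence_minutes = minutes,
                 end_frame = NA_integer_, censored = censored,
                 zero_at_start = FALSE),
            class = "persistence_result")
}

# Build a persistence trace whose frames have prescribed fitted amplitudes
# (noise-free synthetic profiles with those amplitudes).
trace_with_amplitudes <- function(amps, frame_interval = 40, baseline = 10) {
  profiles <- lapply(seq_along(amps), function(i) {
    synth_profile(synth_cell_params(amplitude = amps[i], baseline = baseline,
                                    sigma = 0.3, noise_sd = 0,
                                    seed = 500L + i))
  })
  persistence_trace(1L, (seq_along(amps) - 1) * frame_interval,
                    lapply(profiles, polarity_record))
}
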