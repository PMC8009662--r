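# Post-division persistence and normalized amplitude dynamics.

test_that("normalized amplitude divides every frame by frame 0", {
  tr <- trace_with_amplitudes(c(100, 50, 25))
  expect_equal(normalized_amplitude_curve(tr), c(1, 0.5, 0.25),
               tolerance = 1e-6)
  tr_const <- trace_with_amplitudes(rep(80, 5))
  expect_equal(normalized_amplitude_curve(tr_const), rep(1, 5),
               tolerance = 1e-6)
  tr0 <- trace_with_amplitudes(c(0, 0))
  expect_error(normalized_amplitude_curve(tr0), "undefined")
})

test_that("the normalized curve follows the generator's half-life law", {
  s <- synth_series_params(n_frames = 6L, half_life = 80,
                           disappearance_time = Inf, frame_interval = 40)
  ts <- synth_profile_series(s, synth_cell_params(noise_sd = 0))
  tr <- persistence_trace(1L, ts$frame_times,
                          lapply(ts$profiles, polarity_record))
  expect_equal(normalized_amplitude_curve(tr), 2^(-(0:5) / 2),
               tolerance = 1e-4)
})

test_that("persistence is read off a low-noise series at the true disappearance", {
  s <- synth_series_params(frame_interval = 40, n_frames = 14L,
                           half_life = 480, disappearance_time = 480)
  ts <- synth_profile_series(s, synth_cell_params(noise_sd = 1, seed = 77L))
  tr <- persistence_trace(1L, ts$frame_times,
                          lapply(ts$profiles, polarity_record))
  res <- measure_persistence(tr)
  expect_identical(res$persistence_minutes, 480)
  expect_false(res$censored)
})

test_that("an always-detectable series is censored at the last frame", {
  tr <- trace_with_amplitudes(rep(100, 10))
  res <- measure_persistence(tr)
  expect_true(res$censored)
  expect_identical(res$persistence_minutes, 9 * 40)
})

test_that("amplitude lost at frame 1 gives persistence of one frame interval", {
  tr <- trace_with_amplitudes(c(100, 0, 0, 0))
  res <- measure_persistence(tr)
  expect_identical(res$persistence_minutes, 40)
  expect_false(res$censored)
})

test_that("an undetectable first frame warns and returns zero persistence", {
  tr <- trace_with_amplitudes(c(0, 0, 0))
  expect_warning(res <- measure_persistence(tr), "frame 0")
  expect_identical(res$persistence_minutes, 0)
  expect_true(res$zero_at_start)
})

test_that("adding signal never shortens measured persistence", {
  base_amps <- c(100, 80, 40, 15, 0, 0, 0, 0)
  tr <- trace_with_amplitudes(base_amps)
  p0 <- measure_persistence(tr)$persistence_minutes
  boosted <- trace_with_amplitudes(base_amps + c(0, 0, 0, 30, 40, 0, 0, 0))
  p1 <- measure_persistence(boosted)$persistence_minutes
  expect_gte(p1, p0)
})

test_that("measured persistence is quantized to the frame grid", {
  set.seed(19)
  for (i in 1:20) {
    amps <- 100 * 2^(-(0:9) / runif(1, 1, 6))
    amps[runif(10) < 0.3] <- 0
    if (amps[1] == 0) amps[1] <- 100
    res <- measure_persistence(trace_with_amplitudes(amps))
    expect_true(res$persistence_minutes %in% ((0:9) * 40))
  }
})

test_that("persistence recovery: within one frame of truth in at least 95% of noisy traces", {
  s <- synth_series_params(frame_interval = 40, n_frames = 14L,
                           half_life = 480, disappearance_time = 480)
  hits <- vapply(1:100, function(i) {
    cell <- synth_cell_params(amplitude = 100, baseline = 10, sigma = 0.3,
                              noise_sd = 10, seed = 40000L + 20L * i)
    ts <- synth_profile_series(s, cell)
    tr <- persistence_trace(i, ts$frame_times,
                            lapply(ts$profiles, polarity_record))
    res <- measure_persistence(tr)
    abs(res$persistence_minutes - 480) <= 40
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("group comparison recovers a known persistence offset", {
  # identical groups: zero difference
  ga <- lapply(1:10, function(i) persistence_result_for_test(i, 40 * i %% 5 * 40 + 80))
  expect_equal(compare_persistence_groups(ga, ga)$mean_difference_minutes, 0)
  # exact 40-minute shift
  gb <- lapply(ga, function(r) persistence_result_for_test(r$cell_id,
                                                           r$persistence_minutes + 40))
  expect_equal(compare_persistence_groups(gb, ga)$mean_difference_minutes, 40)
  # 120-minute true offset with frame quantization, 20 seeded replicates
  est <- vapply(1:20, function(rep_i) {
    set.seed(900L + rep_i)
    base <- 40 * pmax(1, round(rnorm(50, 8, 2)))
    a <- lapply(seq_along(base), function(i)
      persistence_result_for_test(i, base[i] + 120))
    b <- lapply(seq_along(base), function(i)
      persistence_result_for_test(i, 40 * pmax(1, round(rnorm(1, 8, 2)))))
    compare_persistence_groups(a, b)$mean_difference_minutes
  }, numeric(1))
  expect_true(all(abs(est - 120) <= 40 + 3 * 40 * 2 / sqrt(50)))
  # all-censored group errors
  gc <- lapply(1:5, function(i) persistence_result_for_test(i, 480, censored = TRUE))
  expect_error(compare_persistence_groups(ga, gc), "uncensored")
})
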