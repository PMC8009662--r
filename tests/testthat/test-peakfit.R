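# Wrapped-Gaussian peak fitting and crescent metrics.

test_that("noise-free model profiles are recovered to 1e-4 relative", {
  cases <- list(c(b = 10, A = 90, mu = pi / 2, sigma = 0.3),
                c(b = 2, A = 40, mu = 5.8, sigma = 0.15),
                c(b = 25, A = 10, mu = 3.1, sigma = 0.8))
  for (cs in cases) {
    pr <- synth_profile(synth_cell_params(baseline = cs[["b"]],
                                          amplitude = cs[["A"]],
                                          center = cs[["mu"]],
                                          sigma = cs[["sigma"]],
                                          noise_sd = 0))
    f <- fit_peak(pr)
    expect_true(f$converged)
    expect_equal(f$b, cs[["b"]], tolerance = 1e-4)
    expect_equal(f$A, cs[["A"]], tolerance = 1e-4)
    expect_equal(f$mu, cs[["mu"]], tolerance = 1e-4)
    expect_equal(f$sigma, cs[["sigma"]], tolerance = 1e-4)
    expect_lt(f$rmse, 1e-6 * cs[["A"]])
  }
})

test_that("a constant profile fits as a flagged zero-amplitude baseline", {
  f <- fit_peak(rep(50, 63))
  expect_identical(f$A, 0)
  expect_identical(f$b, 50)
  expect_true(f$converged)
  expect_true(f$degenerate)
})

test_that("width recovery stays within 10% median error at 10% noise", {
  true_sigma <- 0.3
  errs <- vapply(1:200, function(i) {
    pr <- synth_profile(synth_cell_params(amplitude = 90, baseline = 10,
                                          sigma = true_sigma,
                                          center = pi / 2, noise_sd = 9,
                                          seed = 3000L + i))
    abs(fit_peak(pr)$sigma - true_sigma) / true_sigma
  }, numeric(1))
  expect_lt(stats::median(errs), 0.10)
})

test_that("amplitude bias stays below 5% at 10% noise", {
  A_hat <- vapply(1:200, function(i) {
    pr <- synth_profile(synth_cell_params(amplitude = 90, baseline = 10,
                                          sigma = 0.3, center = pi / 2,
                                          noise_sd = 9, seed = 6000L + i))
    fit_peak(pr)$A
  }, numeric(1))
  expect_lt(abs(mean(A_hat) - 90) / 90, 0.05)
})

test_that("scaling intensities scales the fitted amplitude and baseline", {
  pr <- synth_profile(synth_cell_params(noise_sd = 2, seed = 31L))
  f1 <- fit_peak(pr)
  pr2 <- pr
  pr2$reporter <- pr$reporter * 5
  f2 <- fit_peak(pr2)
  expect_equal(f2$A, 5 * f1$A, tolerance = 1e-3)
  expect_equal(f2$b, 5 * f1$b, tolerance = 1e-3)
  expect_equal(f2$mu, f1$mu, tolerance = 1e-4)
  expect_equal(f2$sigma, f1$sigma, tolerance = 1e-4)
})

test_that("crescent metrics follow the FWHM closed form", {
  f <- fit_peak(synth_profile(synth_cell_params(amplitude = 90,
                                                baseline = 10, sigma = 0.3,
                                                noise_sd = 0)))
  cm <- crescent_metrics(f)
  expect_equal(cm$crescent_fraction, 2 * 0.3 * sqrt(2 * log(2)) / (2 * pi),
               tolerance = 1e-3)
  expect_equal(cm$peak_height, 90, tolerance = 1e-3)
  # zero amplitude: no crescent
  cm0 <- crescent_metrics(fit_peak(rep(7, 63)))
  expect_identical(cm0$crescent_fraction, 0)
  expect_identical(cm0$peak_height, 0)
  # a bump wider than the circle caps at the full perimeter
  wide <- peak_fit_for_test(A = 10, sigma = 2 * pi)
  expect_identical(crescent_metrics(wide)$crescent_fraction, 1)
})
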