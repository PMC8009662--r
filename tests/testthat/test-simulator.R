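# Branching simulator and its analytic stomatal-index oracle.

test_that("expected_si matches closed forms and brute-force summation", {
  expect_identical(expected_si(0), 0.5)
  expect_equal(expected_si(0.5, Inf), 1 / 3)
  expect_equal(expected_si(0.5, 1), 0.4)
  expect_identical(expected_si(1, 3), 1 / 5)
  expect_error(expected_si(1, Inf), "finite")
  for (p in c(0.2, 0.5, 0.8)) {
    for (m in c(1, 3, 5, 50)) {
      expect_equal(expected_si(p, m),
                   1 / (e_rounds_bruteforce(p, m) + 2), tolerance = 1e-10)
    }
  }
})

test_that("without amplification or spacing, SI is exactly one half", {
  res <- simulate_lineages(sim_params(n_founders = 1000L, p_amp = 0,
                                      p_spacing = 0, seed = 2L),
                           record = FALSE)
  expect_identical(res$stomatal_index, 0.5)
  expect_identical(res$total_cells, 3000L)   # 2 guards + 1 pavement each
})

test_that("the simulator is deterministic given the seed", {
  p <- sim_params(n_founders = 500L, p_amp = 0.6, p_spacing = 0.15,
                  seed = 77L)
  a <- simulate_lineages(p, record = FALSE)
  b <- simulate_lineages(p, record = FALSE)
  expect_identical(a$composition, b$composition)
  expect_identical(a$stomatal_index, b$stomatal_index)
  expect_identical(a$amplifying_rounds, b$amplifying_rounds)
})

test_that("simulated SI agrees with the analytic oracle within 3 bootstrap SEs", {
  for (p_amp in c(0, 0.25, 0.5, 0.75)) {
    res <- simulate_lineages(sim_params(n_founders = 100000L, p_amp = p_amp,
                                        p_spacing = 0, max_rounds = 5L,
                                        seed = 50L + round(100 * p_amp)),
                             record = FALSE)
    units <- res$amplifying_rounds + 2
    boot <- vapply(1:200, function(b) {
      set.seed(7000L + b)
      length(units) / sum(sample(units, replace = TRUE))
    }, numeric(1))
    se <- stats::sd(boot)
    expect_lt(abs(res$stomatal_index - expected_si(p_amp, 5L)),
              max(3 * se, 1e-12))
  }
})

test_that("SI falls and cell number rises with the amplifying probability", {
  sw <- sweep_simulation(p_amp = c(0, 0.25, 0.5, 0.75), p_spacing = 0,
                         n_founders = 20000L, max_rounds = 5L, seed = 3L)
  expect_true(all(diff(sw$stomatal_index) < 0))
  expect_true(all(diff(sw$total_cells) > 0))
  expect_true(all(diff(sw$expected_si) < 0))
})

test_that("spacing divisions add cells at fixed amplification", {
  a <- sweep_simulation(p_amp = 0.5, p_spacing = 0, n_founders = 5000L,
                        seed = 11L)
  b <- sweep_simulation(p_amp = 0.5, p_spacing = 0.3, n_founders = 5000L,
                        seed = 11L)
  expect_gt(b$total_cells, a$total_cells)
})

test_that("cells equal founders plus divisions in every simulated lineage", {
  set.seed(4)
  for (i in 1:8) {
    # subcritical: p_spacing * (E[rounds] + 1) < 1
    pp <- sim_params(n_founders = sample(50:500, 1),
                     p_amp = runif(1, 0, 0.85), p_spacing = runif(1, 0, 0.2),
                     max_rounds = sample(2:4, 1), seed = 1000L + i)
    res <- simulate_lineages(pp, record = FALSE)
    expect_identical(res$total_cells, pp$n_founders + res$n_divisions)
  }
})

test_that("simulator lineage records pass validation", {
  res <- simulate_lineages(sim_params(n_founders = 80L, p_amp = 0.6,
                                      p_spacing = 0.25, seed = 6L))
  expect_length(validate_lineage(res$record), 0)
})

test_that("scenario presets keep the qualitative composition ordering", {
  wt <- simulate_lineages(sim_scenario("wild-type", n_founders = 20000L,
                                       seed = 5L), record = FALSE)
  eth <- simulate_lineages(sim_scenario("high-ethylene", n_founders = 20000L,
                                        seed = 5L), record = FALSE)
  glc <- simulate_lineages(sim_scenario("high-glucose", n_founders = 20000L,
                                        seed = 5L), record = FALSE)
  # fewer amplifying divisions: higher SI and fewer cells
  expect_gt(eth$stomatal_index, wt$stomatal_index)
  expect_lt(glc$stomatal_index, wt$stomatal_index)
  expect_lt(eth$total_cells, wt$total_cells)
  expect_gt(glc$total_cells, wt$total_cells)
})
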