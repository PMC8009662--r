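# Synthetic lineage generator: forced paths, truth labels, geometric law.

test_that("the forced path gives one entry ACD, one GMC SCD, one stoma and one pavement cell", {
  rec <- generate_lineage(synth_lineage_params(n_founders = 1L, p_entry = 1,
                                               p_amp = 0, p_spacing = 0,
                                               max_steps = 8L))
  expect_length(validate_lineage(rec), 0)
  expect_identical(sort(rec$divisions$type), c("entry", "gmc_scd"))
  final <- rec$cells$state[rec$cells$timepoint == max(rec$cells$timepoint)]
  expect_identical(sum(final == "guard_cell"), 2L)
  expect_identical(sum(final == "pavement"), 1L)
  expect_length(final, 3L)
})

test_that("with p_amp = 1 the meristemoid line amplifies at every step it exists", {
  rec <- generate_lineage(synth_lineage_params(n_founders = 1L, p_entry = 1,
                                               p_amp = 1, p_spacing = 0,
                                               max_steps = 3L))
  # window: entry at t=1, then an amplifying division at every later step
  expect_identical(sum(rec$divisions$type == "amplifying"),
                   2L)  # steps 2 and 3
  expect_length(validate_lineage(rec), 0)
})

test_that("division-type counts sum to the division total and parents are unique", {
  rec <- generate_lineage(synth_lineage_params(n_founders = 150L,
                                               p_amp = 0.5, p_spacing = 0.2,
                                               max_steps = 7L, seed = 5L))
  expect_length(validate_lineage(rec), 0)
  expect_identical(sum(table(rec$divisions$type)), nrow(rec$divisions))
  first <- rec$cells[!duplicated(rec$cells$cell_id), ]
  non_founders <- first[!is.na(first$parent_id), ]
  expect_true(all(table(non_founders$cell_id) == 1L))
  expect_true(all(non_founders$parent_id %in% first$cell_id))
})

test_that("generation is deterministic and seeds matter", {
  p <- synth_lineage_params(n_founders = 40L, p_amp = 0.6, p_spacing = 0.1,
                            max_steps = 6L, seed = 8L)
  expect_identical(generate_lineage(p)$cells, generate_lineage(p)$cells)
  p2 <- p; p2$seed <- 9L
  expect_false(identical(generate_lineage(p)$cells,
                         generate_lineage(p2)$cells))
})

test_that("mean amplifying divisions per founder follows the geometric law", {
  # p/(1-p) = 1 for p = 0.5; window long enough that truncation is
  # negligible; cross-checked against brute-force mass summation
  n <- 10000L
  rec <- generate_lineage(synth_lineage_params(n_founders = n, p_amp = 0.5,
                                               p_spacing = 0,
                                               max_steps = 30L, seed = 21L))
  n_amp <- sum(rec$divisions$type == "amplifying")
  mean_amp <- n_amp / n
  expect_equal(e_rounds_bruteforce(0.5, 28), 1, tolerance = 1e-6)
  se <- sqrt(2 / n)   # geometric variance p/(1-p)^2 = 2
  expect_lt(abs(mean_amp - 1), 3 * se)
})
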