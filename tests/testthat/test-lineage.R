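# Lineage records: validation, classification, summaries.

make_toy_record <- function() {
  # founder 1 -> (2 meristemoid, 3 SLGC) at t1; 2 -> GMC -> (4, 5) guards;
  # 3 -> pavement
  cells <- data.frame(
    cell_id = c(1L, 2L, 2L, 3L, 3L, 3L, 4L, 5L),
    timepoint = c(0L, 1L, 2L, 1L, 2L, 3L, 3L, 3L),
    state = c("protodermal", "meristemoid", "GMC", "SLGC", "pavement",
              "pavement", "guard_cell", "guard_cell"),
    polarity_call = c("polarized", "absent", "depolarized", "absent",
                      "absent", "absent", "absent", "absent"),
    parent_id = c(NA, 1L, 1L, 1L, 1L, 1L, 2L, 2L),
    stringsAsFactors = FALSE)
  divisions <- data.frame(parent_id = c(1L, 2L), daughter1 = c(2L, 4L),
                          daughter2 = c(3L, 5L), timepoint = c(1L, 3L),
                          type = c("entry", "gmc_scd"),
                          stringsAsFactors = FALSE)
  lineage_record(cells, divisions, timepoints = 0:3)
}

test_that("generator output validates cleanly; corrupted records do not", {
  rec <- generate_lineage(synth_lineage_params(n_founders = 60L,
                                               p_amp = 0.5, p_spacing = 0.2,
                                               max_steps = 6L, seed = 2L))
  expect_length(validate_lineage(rec), 0)

  # three-daughter division
  bad <- make_toy_record()
  extra <- data.frame(cell_id = 6L, timepoint = 1L, state = "SLGC",
                      polarity_call = "absent", parent_id = 1L,
                      stringsAsFactors = FALSE)
  bad$cells <- rbind(bad$cells, extra)
  expect_true(any(grepl("more than 2 daughters", validate_lineage(bad))))

  # illegal state transition: meristemoid -> pavement
  bad2 <- make_toy_record()
  bad2$cells$state[bad2$cells$cell_id == 2L & bad2$cells$timepoint == 2L] <-
    "pavement"
  expect_true(any(grepl("illegal state transition meristemoid -> pavement",
                        validate_lineage(bad2))))

  # lone guard cell
  bad3 <- make_toy_record()
  bad3$cells$state[bad3$cells$cell_id == 5L] <- "pavement"
  expect_true(any(grepl("guard-cell sibling", validate_lineage(bad3))))
})

test_that("division classification follows parent state and polarity", {
  expect_identical(classify_division("meristemoid",
                                     c("meristemoid", "SLGC"),
                                     "polarized")$type, "amplifying")
  expect_identical(classify_division("SLGC", c("meristemoid", "SLGC"),
                                     "polarized")$type, "spacing")
  expect_identical(classify_division("protodermal",
                                     c("meristemoid", "SLGC"),
                                     "polarized")$type, "entry")
  expect_identical(classify_division("GMC", c("guard_cell", "guard_cell"),
                                     "depolarized")$type, "gmc_scd")
  # contradictions are unlabeled with a reason
  conflict <- classify_division("GMC", c("guard_cell", "guard_cell"),
                                "polarized")
  expect_true(is.na(conflict$type))
  expect_match(conflict$reason, "polarized")
  conflict2 <- classify_division("meristemoid", c("meristemoid", "SLGC"),
                                 "depolarized")
  expect_true(is.na(conflict2$type))
})

test_that("classification recovers all true labels on clean synthetic lineages", {
  rec <- generate_lineage(synth_lineage_params(n_founders = 3000L,
                                               p_amp = 0.6, p_spacing = 0.1,
                                               max_steps = 8L, seed = 14L))
  expect_gt(nrow(rec$divisions), 10000L)
  cl <- classify_divisions(rec)
  expect_identical(cl$type, rec$divisions$type)
})

test_that("corrupted polarity calls are flagged, never silently mislabeled", {
  rec <- generate_lineage(synth_lineage_params(n_founders = 400L,
                                               p_amp = 0.5, p_spacing = 0.1,
                                               max_steps = 7L, seed = 15L))
  cc <- rec$cells
  # flip 10% of the informative polarity calls
  set.seed(99)
  informative <- which(cc$polarity_call != "absent")
  flip <- sample(informative, round(0.1 * length(informative)))
  cc$polarity_call[flip] <- ifelse(cc$polarity_call[flip] == "polarized",
                                   "depolarized", "polarized")
  rec2 <- lineage_record(cc, rec$divisions, rec$timepoints)
  cl <- classify_divisions(rec2)
  ok <- !is.na(cl$type)
  # every labeled division is labeled correctly; corrupted ones unlabeled
  expect_identical(cl$type[ok], rec$divisions$type[ok])
  expect_gt(sum(!ok), 0)
  expect_identical(sum(!ok) + sum(ok), nrow(rec$divisions))
})

test_that("the forced-path summary has the expected fractions and histogram", {
  rec <- generate_lineage(synth_lineage_params(n_founders = 1L, p_amp = 0,
                                               p_spacing = 0,
                                               max_steps = 8L))
  s <- summarize_divisions(rec)
  expect_equal(unname(s$fractions[c("entry", "gmc_scd")]), c(0.5, 0.5))
  expect_identical(unname(s$meristemoid_histogram["0"]), 1L)
  expect_identical(s$total_divisions, 2L)

  rec2 <- generate_lineage(synth_lineage_params(n_founders = 1L, p_amp = 1,
                                                p_spacing = 0,
                                                max_steps = 3L))
  s2 <- summarize_divisions(rec2)
  expect_identical(unname(s2$meristemoid_histogram["2"]), 1L)
})

test_that("the amplifying fraction among meristemoid divisions matches the generator rate", {
  n <- 10000L
  rec <- generate_lineage(synth_lineage_params(n_founders = n, p_amp = 0.5,
                                               p_spacing = 0,
                                               max_steps = 30L, seed = 23L))
  s <- summarize_divisions(rec)
  # each meristemoid decision is amplify (ACD) vs differentiate (-> GMC SCD)
  n_m <- s$counts[["amplifying"]] + s$counts[["gmc_scd"]]
  frac <- s$counts[["amplifying"]] / n_m
  se <- sqrt(0.25 / n_m)
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("stomatal index counts a guard-cell pair as one unit", {
  expect_equal(stomatal_index(list(stomata = 2, other = 8)), 0.2)
  expect_equal(stomatal_index(list(stomata = 0, other = 10)), 0)
  expect_error(stomatal_index(list(stomata = 0, other = 0)), "empty")
  # forced path: every founder yields 1 stoma + 1 pavement cell -> SI = 0.5
  for (nf in c(1L, 7L, 40L)) {
    rec <- generate_lineage(synth_lineage_params(n_founders = nf, p_amp = 0,
                                                 p_spacing = 0,
                                                 max_steps = 8L, seed = nf))
    expect_equal(stomatal_index(rec), 0.5)
  }
})

test_that("cell counts track founders plus completed divisions", {
  rec <- make_toy_record()
  expect_identical(unname(cell_count_trajectory(rec)), c(1L, 2L, 2L, 3L))
  # no divisions: constant counts
  lone <- lineage_record(
    data.frame(cell_id = 1L, timepoint = 0:2, state = "pavement",
               polarity_call = "absent", parent_id = NA_integer_),
    make_toy_record()$divisions[0, ], timepoints = 0:2)
  expect_identical(unname(cell_count_trajectory(lone)), c(1L, 1L, 1L))
  # forced path, full window: 3 cells at the end
  rec3 <- generate_lineage(synth_lineage_params(n_founders = 1L, p_amp = 0,
                                                p_spacing = 0,
                                                max_steps = 8L))
  ct <- cell_count_trajectory(rec3)
  expect_identical(unname(ct[length(ct)]), 3L)
  # conservation at every timepoint
  ndiv <- vapply(as.integer(names(ct)),
                 function(tt) sum(rec3$divisions$timepoint <= tt),
                 integer(1))
  expect_identical(unname(ct), 1L + ndiv)
})

test_that("SI identity holds for spacing-free lineages", {
  res <- simulate_lineages(sim_params(n_founders = 300L, p_amp = 0.55,
                                      p_spacing = 0, max_rounds = 5L,
                                      seed = 33L))
  n_i <- res$amplifying_rounds
  expect_length(n_i, 300L)
  expect_equal(res$stomatal_index, 300 / sum(n_i + 2))
  expect_equal(stomatal_index(res$record), res$stomatal_index)
})
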