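# Stochastic branching simulator of stomatal-lineage progression: the
# amplifying/spacing probabilities set the SCD/ACD balance, which in turn
# sets the stomatal index and the epidermal cell number.

#' Simulator parameters
#'
#' @param n_founders Number of founder cells.
#' @param p_entry Probability a founder enters the stomatal lineage.
#' @param p_amp Probability a meristemoid performs an amplifying ACD at
#'   each round (before it has exhausted `max_rounds` rounds).
#' @param p_spacing Probability an SLGC performs a spacing ACD.
#' @param max_rounds Maximum amplifying rounds per meristemoid line; a
#'   line that reaches the cap differentiates into a GMC.
#' @param seed Integer seed; the simulation is deterministic given it.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_founders = 1000L, p_entry = 1, p_amp = 0.5,
                       p_spacing = 0, max_rounds = 5L, seed = 1L) {
  p <- list(n_founders = as.integer(n_founders),
            p_entry = as.numeric(p_entry), p_amp = as.numeric(p_amp),
            p_spacing = as.numeric(p_spacing),
            max_rounds = as.integer(max_rounds), seed = as.integer(seed))
  stopifnot(p$n_founders >= 1L,
            p$p_entry >= 0, p$p_entry <= 1, p$p_amp >= 0, p$p_amp <= 1,
            p$p_spacing >= 0, p$p_spacing <= 1,
            p$max_rounds >= 1L, p$seed >= 0L, p$seed < 2^30)
  class(p) <- "sim_params"
  p
}

#' Scenario presets for the simulator
#'
#' Illustrative parameterizations of the division balance: "wild-type"
#' (balanced amplification), "high-ethylene" (reduced amplifying-ACD
#' probability, shifting the balance towards SCDs: higher stomatal index,
#' fewer cells) and "high-glucose" (increased amplifying-ACD probability:
#' lower stomatal index, more cells). The probabilities are constrained
#' only by these qualitative orderings, not calibrated to measurements.
#'
#' @param name One of "wild-type", "high-ethylene", "high-glucose".
#' @param n_founders,seed Passed through to [sim_params()].
#' @return A [sim_params()] object.
#' @export
sim_scenario <- function(name = c("wild-type", "high-ethylene",
                                  "high-glucose"),
                         n_founders = 1000L, seed = 1L) {
  name <- match.arg(name)
  p_amp <- switch(name, "wild-type" = 0.5, "high-ethylene" = 0.25,
                  "high-glucose" = 0.7)
  sim_params(n_founders = n_founders, p_entry = 1, p_amp = p_amp,
             p_spacing = 0.1, max_rounds = 5L, seed = seed)
}

#' Run the lineage simulator
#'
#' Runs every founder through the stomatal-lineage state machine to
#' absorption (meristemoid lines differentiate after `max_rounds`
#' amplifying rounds) and summarizes the resulting tissue composition.
#'
#' @param params A [sim_params()] object.
#' @param record If `TRUE` (default) also expand and return the full
#'   long-format [lineage_record()]; set `FALSE` to skip the expansion for
#'   very large simulations.
#' @return An object of class `sim_result`: list with `composition`
#'   (stomata, pavement, protodermal, undifferentiated), `divisions`
#'   (counts per type), `stomatal_index`, `total_cells` (guard-cell pair =
#'   2 cells), `amplifying_rounds` (integer vector, one per meristemoid
#'   line), `record` (a [lineage_record()] or `NULL`), and `params`.
#' @export
simulate_lineages <- function(params, record = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  eng <- run_lineage_engine(params$n_founders, params$p_entry,
                            params$p_amp, params$p_spacing,
                            cap_mode = "differentiate",
                            line_max_rounds = params$max_rounds,
                            seed = params$seed)
  fs <- final_states(eng)
  n_stomata <- sum(fs == "guard_cell") / 2
  n_pav <- sum(fs == "pavement") + sum(fs == "SLGC")
  n_proto <- sum(fs == "protodermal")
  n_undiff <- sum(fs %in% c("meristemoid", "GMC"))
  div_types <- eng$cells$div_type[!is.na(eng$cells$div_type)]
  div_counts <- vapply(DIVISION_TYPES, function(tt) sum(div_types == tt),
                       integer(1))
  si <- stomatal_index(list(stomata = n_stomata,
                            other = n_pav + n_proto))
  structure(list(composition = c(stomata = n_stomata, pavement = n_pav,
                                 protodermal = n_proto,
                                 undifferentiated = n_undiff),
                 divisions = div_counts,
                 stomatal_index = si,
                 total_cells = length(fs),
                 amplifying_rounds = unname(line_amplifying_counts(eng)),
                 record = if (record) engine_to_record(eng) else NULL,
                 params = params,
                 n_divisions = length(div_types)),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result>", x$params$n_founders, "founders | SI =",
      round(x$stomatal_index, 4), "|", x$total_cells, "cells |",
      x$n_divisions, "divisions\n")
  print(x$composition)
  invisible(x)
}

#' Expected stomatal index without spacing divisions
#'
#' Analytic oracle for the simulator in the `p_spacing = 0` regime. Each
#' entered founder performs `n` amplifying rounds with `n` following a
#' geometric law (continue with probability `p_amp`) truncated at
#' `max_rounds`, then differentiates; its lineage contributes one stoma
#' and `n + 2` counting units, so in the many-founder limit
#' `SI = 1 / (E[n] + 2)` with
#' `E[n] = sum_{k=1..max_rounds} p_amp^k`.
#'
#' @param p_amp Amplifying probability per round, in `[0, 1]`.
#' @param max_rounds Cap on amplifying rounds; may be `Inf` when
#'   `p_amp < 1`.
#' @return The limiting stomatal index.
#' @export
expected_si <- function(p_amp, max_rounds = Inf) {
  stopifnot(p_amp >= 0, p_amp <= 1)
  if (p_amp == 1 && !is.finite(max_rounds)) {
    stop("p_amp = 1 requires a finite `max_rounds`")
  }
  e_n <- if (p_amp == 1) {
    max_rounds
  } else if (is.finite(max_rounds)) {
    p_amp * (1 - p_amp^max_rounds) / (1 - p_amp)
  } else {
    p_amp / (1 - p_amp)
  }
  1 / (e_n + 2)
}

#' Sweep the simulator over a parameter grid
#'
#' Runs one simulation per grid point with a deterministic per-point seed
#' derived from `seed`, and tabulates stomatal index and cell number
#' against the division-balance parameters.
#'
#' @param p_amp Vector of amplifying probabilities.
#' @param p_spacing Vector of spacing probabilities (crossed with `p_amp`).
#' @param n_founders Founders per grid point.
#' @param max_rounds Amplifying-round cap.
#' @param seed Master seed.
#' @return Data frame with one row per grid point: `p_amp`, `p_spacing`,
#'   `stomatal_index`, `expected_si` (analytic, `NA` when
#'   `p_spacing > 0`), `total_cells`, `stomata`, `total_divisions`, `seed`.
#' @export
sweep_simulation <- function(p_amp = c(0, 0.25, 0.5, 0.75), p_spacing = 0,
                             n_founders = 10000L, max_rounds = 5L,
                             seed = 1L) {
  grid <- expand.grid(p_amp = p_amp, p_spacing = p_spacing,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    pp <- sim_params(n_founders = n_founders, p_amp = grid$p_amp[i],
                     p_spacing = grid$p_spacing[i], max_rounds = max_rounds,
                     seed = seed + i)
    res <- simulate_lineages(pp, record = FALSE)
    data.frame(p_amp = grid$p_amp[i], p_spacing = grid$p_spacing[i],
               stomatal_index = res$stomatal_index,
               expected_si = if (grid$p_spacing[i] == 0)
                 expected_si(grid$p_amp[i], max_rounds) else NA_real_,
               total_cells = res$total_cells,
               stomata = unname(res$composition["stomata"]),
               total_divisions = res$n_divisions,
               seed = seed + i)
  })
  do.call(rbind, rows)
}
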