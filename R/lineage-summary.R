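# Division classification and tissue summaries.

#' Classify a single division
#'
#' Division-type logic for lineage tracing: symmetric GMC divisions read out
#' as a depolarized parent producing a guard-cell pair, while asymmetric
#' divisions (entry, amplifying, spacing) have a polarized parent crescent
#' and are subtyped by the parent's state. Contradictory evidence (a
#' polarized parent producing guard cells, or a depolarized non-GMC parent
#' producing non-guard daughters) yields `unlabeled` with a reason.
#'
#' @param parent_state Parent state at the timepoint before the division.
#' @param daughter_states Character vector (2) of daughter states at birth.
#' @param polarity_call Parent polarity call at the timepoint before the
#'   division: "polarized", "depolarized" or "absent".
#' @param daughter_sizes Optional numeric vector (2) of daughter areas;
#'   advisory only (asymmetric daughters are expected for ACDs), not used
#'   for the call.
#' @return A list with `type` (one of entry, amplifying, spacing, gmc_scd,
#'   or `NA` for unlabeled) and `reason` (`NA` or why it is unlabeled).
#' @export
classify_division <- function(parent_state, daughter_states,
                              polarity_call = "absent",
                              daughter_sizes = NULL) {
  stopifnot(length(daughter_states) == 2L)
  guard_pair <- all(daughter_states == "guard_cell")
  if (guard_pair || parent_state == "GMC") {
    if (identical(polarity_call, "polarized")) {
      return(list(type = NA_character_,
                  reason = "polarized parent with guard-cell daughters"))
    }
    if (!guard_pair) {
      return(list(type = NA_character_,
                  reason = "GMC parent without a guard-cell pair"))
    }
    return(list(type = "gmc_scd", reason = NA_character_))
  }
  if (identical(polarity_call, "depolarized")) {
    return(list(type = NA_character_,
                reason = "depolarized parent without guard-cell daughters"))
  }
  type <- switch(parent_state,
                 protodermal = "entry",
                 meristemoid = "amplifying",
                 SLGC = "spacing",
                 NA_character_)
  if (is.na(type)) {
    return(list(type = NA_character_,
                reason = paste0("parent state '", parent_state,
                                "' cannot divide asymmetrically")))
  }
  list(type = type, reason = NA_character_)
}

# Parent state / polarity at (division timepoint - 1) and daughter states at
# birth, for every division of a record.
division_evidence <- function(record) {
  cc <- record$cells
  dv <- record$divisions
  key <- paste(cc$cell_id, cc$timepoint)
  pidx <- match(paste(dv$parent_id, dv$timepoint - 1), key)
  d1idx <- match(paste(dv$daughter1, dv$timepoint), key)
  d2idx <- match(paste(dv$daughter2, dv$timepoint), key)
  data.frame(parent_state = cc$state[pidx],
             polarity_call = cc$polarity_call[pidx],
             daughter1_state = cc$state[d1idx],
             daughter2_state = cc$state[d2idx],
             stringsAsFactors = FALSE)
}

#' Classify every division of a lineage record
#'
#' Applies [classify_division()] to each division, reading the parent state
#' and polarity call at the timepoint before the division and the daughter
#' states at their first appearance.
#'
#' @param record A [lineage_record()].
#' @return Data frame with one row per division: `parent_id`, `timepoint`,
#'   `type` (`NA` = unlabeled), `reason`.
#' @export
classify_divisions <- function(record) {
  stopifnot(inherits(record, "lineage_record"))
  dv <- record$divisions
  ev <- division_evidence(record)
  guard_pair <- ev$daughter1_state == "guard_cell" &
    ev$daughter2_state == "guard_cell"
  is_gmc_side <- guard_pair | ev$parent_state == "GMC"
  pol <- ev$polarity_call
  type <- rep(NA_character_, nrow(dv))
  reason <- rep(NA_character_, nrow(dv))

  conflict1 <- is_gmc_side & pol == "polarized"
  reason[conflict1] <- "polarized parent with guard-cell daughters"
  bad_gmc <- is_gmc_side & !conflict1 & !guard_pair
  reason[bad_gmc] <- "GMC parent without a guard-cell pair"
  ok_gmc <- is_gmc_side & !conflict1 & guard_pair
  type[ok_gmc] <- "gmc_scd"

  acd <- !is_gmc_side
  conflict2 <- acd & pol == "depolarized"
  reason[conflict2] <- "depolarized parent without guard-cell daughters"
  sub <- c(protodermal = "entry", meristemoid = "amplifying",
           SLGC = "spacing")
  known <- acd & !conflict2 & ev$parent_state %in% names(sub)
  type[known] <- unname(sub[ev$parent_state[known]])
  odd <- acd & !conflict2 & !known
  reason[odd] <- paste0("parent state '", ev$parent_state[odd],
                        "' cannot divide asymmetrically")

  data.frame(parent_id = dv$parent_id, timepoint = dv$timepoint,
             type = type, reason = reason, stringsAsFactors = FALSE)
}

#' Summarize the divisions of a lineage record
#'
#' Tissue-level summary: counts and fractions per division type (computed
#' over labeled divisions; unlabeled ones are reported separately and
#' excluded from the fractions), the histogram of amplifying rounds per
#' meristemoid line, the stomatal index of the final composition, and the
#' cell-count trajectory.
#'
#' @param record A [lineage_record()].
#' @param use_true_labels If `TRUE` (default) use the type labels stored in
#'   the record where present; otherwise re-classify every division with
#'   [classify_divisions()].
#' @param histogram_breaks Upper class limits for the amplification
#'   histogram; the default bins rounds as 0, 1, 2, >=3.
#' @return A list of class `division_summary` with `counts`, `fractions`,
#'   `total_divisions`, `n_unlabeled`, `meristemoid_histogram`,
#'   `stomatal_index`, `cell_counts`.
#' @export
summarize_divisions <- function(record, use_true_labels = TRUE,
                                histogram_breaks = c(0, 1, 2, Inf)) {
  stopifnot(inherits(record, "lineage_record"))
  dv <- record$divisions
  types <- dv$type
  if (!use_true_labels || all(is.na(types))) {
    types <- classify_divisions(record)$type
  }
  counts <- vapply(DIVISION_TYPES, function(tt) sum(types == tt, na.rm = TRUE),
                   integer(1))
  n_lab <- sum(counts)
  fractions <- if (n_lab > 0) counts / n_lab else counts * NA_real_

  rounds <- meristemoid_rounds(record, types)
  hist_labels <- character(length(histogram_breaks))
  for (i in seq_along(histogram_breaks)) {
    hist_labels[i] <- if (is.finite(histogram_breaks[i]))
      as.character(histogram_breaks[i]) else
        paste0(">=", histogram_breaks[i - 1] + 1)
  }
  bins <- findInterval(rounds, c(-Inf, histogram_breaks[-length(histogram_breaks)] + 0.5))
  hist <- vapply(seq_along(histogram_breaks),
                 function(i) sum(bins == i), integer(1))
  names(hist) <- hist_labels

  structure(list(counts = counts, fractions = fractions,
                 total_divisions = nrow(dv),
                 n_unlabeled = sum(is.na(types)),
                 meristemoid_histogram = hist,
                 stomatal_index = stomatal_index(record),
                 cell_counts = cell_count_trajectory(record)),
            class = "division_summary")
}

#' @export
print.division_summary <- function(x, ...) {
  cat("<division_summary>", x$total_divisions, "divisions (",
      x$n_unlabeled, "unlabeled )\n")
  print(round(rbind(count = x$counts, fraction = x$fractions), 3))
  cat("amplifying rounds per meristemoid line:\n")
  print(x$meristemoid_histogram)
  cat("stomatal index:", round(x$stomatal_index, 4), "\n")
  invisible(x)
}

# Amplifying-division count per meristemoid line. A line starts at the
# meristemoid daughter of an entry or spacing division and continues through
# the meristemoid daughter of each amplifying division.
meristemoid_rounds <- function(record, types = record$divisions$type) {
  cc <- record$cells
  dv <- record$divisions
  first_rows <- cc[!duplicated(cc$cell_id), ]
  birth_state <- first_rows$state
  names(birth_state) <- as.character(first_rows$cell_id)
  # vectorized meristemoid-daughter lookup for a vector of division indices
  m_daughter <- function(i) {
    d1 <- dv$daughter1[i]; d2 <- dv$daughter2[i]
    d1_is_m <- birth_state[as.character(d1)] == "meristemoid"
    out <- ifelse(d1_is_m, d1, d2)
    d2_is_m <- birth_state[as.character(d2)] == "meristemoid"
    out[!d1_is_m & !d2_is_m] <- NA
    out
  }
  starts <- which(types %in% c("entry", "spacing"))
  amp <- !is.na(types) & types == "amplifying"
  amp_parent <- dv$parent_id[amp]
  amp_idx <- which(amp)
  # breadth-first over line generations: all line heads advance in parallel
  heads <- if (length(starts)) m_daughter(starts) else integer(0)
  rounds <- integer(length(starts))
  repeat {
    nxt <- amp_idx[match(heads, amp_parent)]
    active <- !is.na(heads) & !is.na(nxt)
    if (!any(active)) break
    rounds[active] <- rounds[active] + 1L
    heads[active] <- m_daughter(nxt[active])
    heads[!active] <- NA
  }
  rounds
}

# States of all cells alive at the final timepoint of the record.
record_final_states <- function(record) {
  cc <- record$cells
  t_end <- max(cc$timepoint)
  cc$state[cc$timepoint == t_end]
}

#' Stomatal index of a final tissue composition
#'
#' The ratio of stomata to all epidermal cells, with a guard-cell pair
#' counted as one stoma and one unit in the denominator. Cells that are
#' still meristemoids or GMCs at the end of the window are treated as
#' undifferentiated and excluded; pavement cells, SLGCs and
#' never-entering protodermal cells count as single epidermal units.
#'
#' @param x A [lineage_record()], or a named composition vector/list with
#'   elements `stomata` and `other` (non-stomatal epidermal units).
#' @return The stomatal index, a fraction in `[0, 1]`.
#' @export
stomatal_index <- function(x) {
  if (inherits(x, "lineage_record")) {
    st <- record_final_states(x)
    n_stomata <- sum(st == "guard_cell") / 2
    n_other <- sum(st %in% c("pavement", "SLGC", "protodermal"))
  } else {
    n_stomata <- x[["stomata"]]
    n_other <- x[["other"]]
  }
  if (n_stomata + n_other == 0) {
    stop("stomatal index undefined for an empty epidermis")
  }
  n_stomata / (n_stomata + n_other)
}

#' Cell-number trajectory of a lineage record
#'
#' Number of living cells at each timepoint of the window. Here a
#' guard-cell pair counts as two cells (total epidermal cell number); the
#' one-stoma-one-unit convention applies only to the stomatal index.
#'
#' @param record A [lineage_record()].
#' @return Named integer vector of cell counts per timepoint.
#' @export
cell_count_trajectory <- function(record) {
  stopifnot(inherits(record, "lineage_record"))
  tab <- table(factor(record$cells$timepoint, levels = record$timepoints))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}
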