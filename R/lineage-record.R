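# Lineage records: long-format per-timepoint cell states plus a division
# table, as produced by lineage tracing (or the synthetic generator).

#' Construct a lineage record
#'
#' @param cells Data frame with columns `cell_id`, `timepoint`, `state`
#'   (one of protodermal, meristemoid, SLGC, GMC, guard_cell, pavement),
#'   `polarity_call` (polarized, depolarized, absent) and `parent_id`
#'   (`NA` for founders); one row per cell per timepoint it is alive.
#' @param divisions Data frame with columns `parent_id`, `daughter1`,
#'   `daughter2`, `timepoint` (when the daughters are first seen) and
#'   `type` (entry, amplifying, spacing, gmc_scd, or `NA` for unlabeled).
#' @param timepoints Ordered vector of the timepoint labels of the tracing
#'   window.
#' @return An object of class `lineage_record`.
#' @export
lineage_record <- function(cells, divisions, timepoints) {
  stopifnot(all(c("cell_id", "timepoint", "state", "polarity_call",
                  "parent_id") %in% names(cells)),
            all(c("parent_id", "daughter1", "daughter2", "timepoint",
                  "type") %in% names(divisions)))
  structure(list(cells = cells, divisions = divisions,
                 timepoints = timepoints),
            class = "lineage_record")
}

#' @export
print.lineage_record <- function(x, ...) {
  cat("<lineage_record>", length(unique(x$cells$cell_id)), "cells |",
      nrow(x$divisions), "divisions |",
      length(x$timepoints), "timepoints\n")
  invisible(x)
}

# Allowed state self/forward transitions between consecutive timepoints.
ALLOWED_TRANSITIONS <- rbind(
  c("protodermal", "protodermal"),
  c("meristemoid", "meristemoid"),
  c("meristemoid", "GMC"),
  c("SLGC", "SLGC"),
  c("SLGC", "pavement"),
  c("GMC", "GMC"),
  c("pavement", "pavement"),
  c("guard_cell", "guard_cell")
)

#' Validate a lineage record
#'
#' Checks the structural invariants of lineage-tracing data: every division
#' has exactly two daughters that appear at the division timepoint; every
#' non-founder cell has exactly one parent and is a daughter of exactly one
#' division; guard cells arise as sibling pairs of gmc_scd divisions; and
#' each cell's state path follows the stomatal-lineage transition graph
#' (protodermal stays protodermal until an entry division; meristemoids
#' stay or become GMCs; SLGCs stay or become pavement; GMCs, pavement and
#' guard cells are otherwise stable).
#'
#' @param record A [lineage_record()].
#' @return Character vector of violation messages; empty means valid.
#' @export
validate_lineage <- function(record) {
  stopifnot(inherits(record, "lineage_record"))
  cc <- record$cells
  dv <- record$divisions
  bad <- character(0)

  # per-cell parent consistency
  first_rows <- cc[!duplicated(cc$cell_id), ]
  par_n <- tapply(cc$parent_id, cc$cell_id, function(p) length(unique(p)))
  if (any(par_n > 1)) {
    bad <- c(bad, paste0("cell ", names(par_n)[par_n > 1],
                         " has inconsistent parent annotations"))
  }

  # divisions: two distinct daughters present, parent disappears
  if (nrow(dv)) {
    lacking <- is.na(dv$daughter1) | is.na(dv$daughter2) |
      dv$daughter1 == dv$daughter2
    if (any(lacking)) {
      bad <- c(bad, paste0("division of cell ", dv$parent_id[lacking],
                           " lacks two distinct daughters"))
    }
    for (col in c("daughter1", "daughter2")) {
      dd <- dv[[col]][!lacking]
      pp <- dv$parent_id[!lacking]
      pr <- first_rows$parent_id[match(dd, first_rows$cell_id)]
      mis <- is.na(pr) | pr != pp
      if (any(mis)) {
        bad <- c(bad, paste0("daughter ", dd[mis], " of cell ", pp[mis],
                             " is missing or mis-parented"))
      }
    }
    # more than 2 daughters recorded for one parent
    kids <- table(first_rows$parent_id[!is.na(first_rows$parent_id)])
    over <- names(kids)[kids > 2]
    if (length(over)) {
      bad <- c(bad, paste0("cell ", over, " has more than 2 daughters"))
    }
    dup_par <- dv$parent_id[duplicated(dv$parent_id)]
    if (length(dup_par)) {
      bad <- c(bad, paste0("cell ", unique(dup_par), " divides twice"))
    }
  }

  # orphan non-founders: parent never appears in the record
  nf <- first_rows[!is.na(first_rows$parent_id), ]
  orphan <- !(nf$parent_id %in% first_rows$cell_id)
  if (any(orphan)) {
    bad <- c(bad, paste0("cell ", nf$cell_id[orphan],
                         " references missing parent ",
                         nf$parent_id[orphan]))
  }

  # guard cells must be sibling pairs from gmc_scd divisions
  guards <- unique(cc$cell_id[cc$state == "guard_cell"])
  if (length(guards)) {
    gpar <- first_rows$parent_id[match(guards, first_rows$cell_id)]
    lonely <- is.na(gpar)
    if (any(lonely)) {
      bad <- c(bad, paste0("guard cell ", guards[lonely], " has no parent"))
    }
    for (p in unique(gpar[!lonely])) {
      sibs <- first_rows$cell_id[!is.na(first_rows$parent_id) &
                                   first_rows$parent_id == p]
      if (!all(sibs %in% guards) || length(sibs) != 2L) {
        bad <- c(bad, paste0("guard cell under parent ", p,
                             " lacks a guard-cell sibling"))
      }
      ty <- dv$type[dv$parent_id == p]
      if (length(ty) == 1L && !is.na(ty) && ty != "gmc_scd") {
        bad <- c(bad, paste0("guard-cell pair under parent ", p,
                             " from a non-gmc_scd division"))
      }
    }
  }

  # state transitions along each cell's own timeline
  ord <- order(cc$cell_id, cc$timepoint)
  cid <- cc$cell_id[ord]; st <- cc$state[ord]
  same <- cid[-1] == cid[-length(cid)]
  from <- st[-length(st)][same]; to <- st[-1][same]
  key <- paste(from, to)
  okkey <- paste(ALLOWED_TRANSITIONS[, 1], ALLOWED_TRANSITIONS[, 2])
  illegal <- !(key %in% okkey)
  if (any(illegal)) {
    bad <- c(bad, paste0("illegal state transition ", from[illegal],
                         " -> ", to[illegal], " (cell ",
                         cid[-1][same][illegal], ")"))
  }

  unknown <- !(cc$state %in% LINEAGE_STATES)
  if (any(unknown)) {
    bad <- c(bad, paste0("unknown state '", unique(cc$state[unknown]), "'"))
  }
  bad
}
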