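# Stochastic stomatal-lineage state machine.
#
# Synchronous rounds t = 0, 1, 2, ...; divisions decided in round t are
# recorded at timepoint t + 1. Per round, in fixed order: GMCs divide
# symmetrically (guard-cell pair), meristemoids draw an amplifying coin
# (else differentiate to GMC), SLGCs draw a spacing coin (else become
# pavement). Founders take a single entry decision at round 0. All draws
# are vectorized, so the engine handles 1e5 founders comfortably.

LINEAGE_STATES <- c("protodermal", "meristemoid", "SLGC", "GMC",
                    "guard_cell", "pavement")
DIVISION_TYPES <- c("entry", "amplifying", "spacing", "gmc_scd")
ACD_TYPES <- c("entry", "amplifying", "spacing")

# cap_mode "truncate":      run exactly `window_steps` rounds; whatever is
#                           still dividing stays in place (tracing window).
# cap_mode "differentiate": meristemoid lines differentiate to GMC once they
#                           have used `line_max_rounds` amplifying rounds;
#                           run to absorption (hard safety cap on rounds).
run_lineage_engine <- function(n_founders, p_entry, p_amp, p_spacing,
                               cap_mode = c("truncate", "differentiate"),
                               window_steps = NULL, line_max_rounds = Inf,
                               seed = 1L) {
  cap_mode <- match.arg(cap_mode)
  set.seed(seed)
  nf <- as.integer(n_founders)

  # growing per-cell vectors (appended round by round, updated in place)
  id <- seq_len(nf)
  parent <- rep(NA_integer_, nf)
  born <- rep(0L, nf)
  s1 <- rep("protodermal", nf)
  s2 <- rep(NA_character_, nf)
  s2_t <- rep(NA_integer_, nf)
  div_t <- rep(NA_integer_, nf)
  div_type <- rep(NA_character_, nf)
  founder <- seq_len(nf)
  line <- rep(NA_integer_, nf)
  next_id <- nf + 1L
  next_line <- 1L

  # active sets (indices into the vectors above)
  act_proto <- seq_len(nf)
  act_m <- integer(0); act_m_rounds <- integer(0)
  act_slgc <- integer(0)
  act_gmc <- integer(0)

  new_cells <- function(n, par, t, state, fndr, lin) {
    ids <- next_id + seq_len(n) - 1L
    next_id <<- next_id + n
    id <<- c(id, ids)
    parent <<- c(parent, par)
    born <<- c(born, rep(t, n))
    s1 <<- c(s1, rep(state, n))
    s2 <<- c(s2, rep(NA_character_, n))
    s2_t <<- c(s2_t, rep(NA_integer_, n))
    div_t <<- c(div_t, rep(NA_integer_, n))
    div_type <<- c(div_type, rep(NA_character_, n))
    founder <<- c(founder, fndr)
    line <<- c(line, lin)
    ids
  }

  hard_cap <- if (cap_mode == "truncate") as.integer(window_steps) else
    max(64L, 8L * min(line_max_rounds, 64L))
  # when p_spacing * (E[amplifying rounds] + 1) >= 1 the branching process
  # is supercritical and grows without bound; refuse to exhaust memory
  max_population <- 5e6
  t <- 0L
  while (t < hard_cap) {
    if (length(act_proto) + length(act_m) + length(act_slgc) +
        length(act_gmc) == 0L) break
    if (length(id) > max_population) {
      stop("lineage population exceeded ", format(max_population,
                                                  scientific = FALSE),
           " cells; the spacing/amplification parameters are ",
           "supercritical (p_spacing * (E[rounds] + 1) >= 1)")
    }

    # cells created or re-fated during round t act from round t + 1 on
    nxt_m <- integer(0); nxt_m_rounds <- integer(0)
    nxt_slgc <- integer(0); nxt_gmc <- integer(0)

    # founders: single entry decision at round 0
    if (t == 0L && length(act_proto)) {
      enter <- stats::runif(length(act_proto)) < p_entry
      ei <- act_proto[enter]
      if (length(ei)) {
        lin <- next_line + seq_along(ei) - 1L
        next_line <- next_line + length(ei)
        m_ids <- new_cells(length(ei), id[ei], t + 1L, "meristemoid",
                           founder[ei], lin)
        s_ids <- new_cells(length(ei), id[ei], t + 1L, "SLGC", founder[ei],
                           rep(NA_integer_, length(ei)))
        div_t[ei] <- t + 1L
        div_type[ei] <- "entry"
        nxt_m <- c(nxt_m, match(m_ids, id))
        nxt_m_rounds <- c(nxt_m_rounds, rep(0L, length(ei)))
        nxt_slgc <- c(nxt_slgc, match(s_ids, id))
      }
      act_proto <- integer(0)  # non-entering founders are terminal
    }

    # GMCs: symmetric division into a guard-cell pair
    if (length(act_gmc)) {
      gi <- act_gmc
      new_cells(length(gi), id[gi], t + 1L, "guard_cell",
                founder[gi], rep(NA_integer_, length(gi)))
      new_cells(length(gi), id[gi], t + 1L, "guard_cell",
                founder[gi], rep(NA_integer_, length(gi)))
      div_t[gi] <- t + 1L
      div_type[gi] <- "gmc_scd"
    }

    # meristemoids: amplify or differentiate
    if (length(act_m)) {
      can_amp <- act_m_rounds < line_max_rounds
      coin <- stats::runif(length(act_m)) < p_amp
      amp <- can_amp & coin
      ai <- act_m[amp]
      di <- act_m[!amp]
      if (length(ai)) {
        m_ids <- new_cells(length(ai), id[ai], t + 1L, "meristemoid",
                           founder[ai], line[ai])
        s_ids <- new_cells(length(ai), id[ai], t + 1L, "SLGC",
                           founder[ai], rep(NA_integer_, length(ai)))
        div_t[ai] <- t + 1L
        div_type[ai] <- "amplifying"
        nxt_m <- c(nxt_m, match(m_ids, id))
        nxt_m_rounds <- c(nxt_m_rounds, act_m_rounds[amp] + 1L)
        nxt_slgc <- c(nxt_slgc, match(s_ids, id))
      }
      if (length(di)) {
        s2[di] <- "GMC"
        s2_t[di] <- t + 1L
        nxt_gmc <- c(nxt_gmc, di)
      }
    }

    # SLGCs: spacing division or pavement fate
    if (length(act_slgc)) {
      coin <- stats::runif(length(act_slgc)) < p_spacing
      si <- act_slgc[coin]
      pi_ <- act_slgc[!coin]
      if (length(si)) {
        lin <- next_line + seq_along(si) - 1L
        next_line <- next_line + length(si)
        m_ids <- new_cells(length(si), id[si], t + 1L, "meristemoid",
                           founder[si], lin)
        s_ids <- new_cells(length(si), id[si], t + 1L, "SLGC",
                           founder[si], rep(NA_integer_, length(si)))
        div_t[si] <- t + 1L
        div_type[si] <- "spacing"
        nxt_m <- c(nxt_m, match(m_ids, id))
        nxt_m_rounds <- c(nxt_m_rounds, rep(0L, length(si)))
        nxt_slgc <- c(nxt_slgc, match(s_ids, id))
      }
      if (length(pi_)) {
        s2[pi_] <- "pavement"
        s2_t[pi_] <- t + 1L
      }
    }

    act_m <- nxt_m; act_m_rounds <- nxt_m_rounds
    act_slgc <- nxt_slgc; act_gmc <- nxt_gmc
    t <- t + 1L
  }

  t_end <- if (cap_mode == "truncate") as.integer(window_steps) else
    max(0L, born, s2_t, div_t, na.rm = TRUE)

  cells <- data.frame(cell_id = id, parent_id = parent, born_t = born,
                      s1 = s1, s2 = s2, s2_t = s2_t,
                      div_t = div_t, div_type = div_type,
                      founder_id = founder, line_id = line,
                      stringsAsFactors = FALSE)
  list(cells = cells, n_founders = nf, t_end = t_end,
       n_lines = next_line - 1L)
}

# Final state of every cell alive at t_end (i.e. cells that never divided).
final_states <- function(engine) {
  cc <- engine$cells
  alive <- is.na(cc$div_t)
  st <- cc$s1
  use2 <- !is.na(cc$s2) & !is.na(cc$s2_t) & cc$s2_t <= engine$t_end
  st[use2] <- cc$s2[use2]
  st[alive]
}

# Amplifying divisions per meristemoid line (named by line id, includes 0s).
line_amplifying_counts <- function(engine) {
  cc <- engine$cells
  if (engine$n_lines == 0L) return(integer(0))
  amp_parents <- cc$cell_id[!is.na(cc$div_type) & cc$div_type == "amplifying"]
  amp_lines <- cc$line_id[match(amp_parents, cc$cell_id)]
  counts <- integer(engine$n_lines)
  if (length(amp_lines)) {
    tb <- table(amp_lines)
    counts[as.integer(names(tb))] <- as.integer(tb)
  }
  names(counts) <- seq_len(engine$n_lines)
  counts
}

# Expand a compact engine record into the long per-timepoint lineage record.
engine_to_record <- function(engine) {
  cc <- engine$cells
  t_end <- engine$t_end
  life_end <- ifelse(is.na(cc$div_t), t_end, cc$div_t - 1L)
  keep <- life_end >= cc$born_t
  cc2 <- cc[keep, ]
  life_end <- life_end[keep]
  n_t <- life_end - cc2$born_t + 1L
  rows_cell <- rep.int(seq_len(nrow(cc2)), n_t)
  tp <- sequence(n_t, from = cc2$born_t)
  state <- cc2$s1[rows_cell]
  has2 <- !is.na(cc2$s2)[rows_cell] & tp >= cc2$s2_t[rows_cell] &
    !is.na(cc2$s2_t[rows_cell])
  state[has2] <- cc2$s2[rows_cell][has2]
  polarity <- rep("absent", length(tp))
  polarity[state == "GMC"] <- "depolarized"
  acd <- !is.na(cc2$div_type[rows_cell]) &
    cc2$div_type[rows_cell] %in% ACD_TYPES &
    tp == (cc2$div_t[rows_cell] - 1L)
  polarity[acd] <- "polarized"
  # the GMC division is read from a depolarized parent
  scd <- !is.na(cc2$div_type[rows_cell]) &
    cc2$div_type[rows_cell] == "gmc_scd" &
    tp == (cc2$div_t[rows_cell] - 1L)
  polarity[scd] <- "depolarized"

  cells_long <- data.frame(cell_id = cc2$cell_id[rows_cell],
                           timepoint = tp, state = state,
                           polarity_call = polarity,
                           parent_id = cc2$parent_id[rows_cell],
                           stringsAsFactors = FALSE)

  div_parents <- cc$cell_id[!is.na(cc$div_t)]
  if (length(div_parents)) {
    dmatch <- cc[!is.na(cc$parent_id), c("cell_id", "parent_id")]
    d1 <- vapply(split(dmatch$cell_id, dmatch$parent_id), `[`, integer(1), 1L)
    d2 <- vapply(split(dmatch$cell_id, dmatch$parent_id), `[`, integer(1), 2L)
    ord <- match(as.character(div_parents), names(d1))
    divisions <- data.frame(parent_id = div_parents,
                            daughter1 = unname(d1[ord]),
                            daughter2 = unname(d2[ord]),
                            timepoint = cc$div_t[match(div_parents, cc$cell_id)],
                            type = cc$div_type[match(div_parents, cc$cell_id)],
                            stringsAsFactors = FALSE)
  } else {
    divisions <- data.frame(parent_id = integer(0), daughter1 = integer(0),
                            daughter2 = integer(0), timepoint = integer(0),
                            type = character(0), stringsAsFactors = FALSE)
  }
  lineage_record(cells_long, divisions, timepoints = 0:t_end)
}

#' Generate a ground-truthed synthetic lineage record
#'
#' Runs the stomatal-lineage state machine over a fixed tracing window of
#' `max_steps` rounds and returns the long-format lineage record with every
#' division labeled with its true type. Cells still dividing when the
#' window closes remain in their last state (meristemoid or GMC), matching
#' what a finite tracing window observes.
#'
#' @param params A [synth_lineage_params()] object.
#' @return A [lineage_record()] whose divisions carry true type labels; the
#'   compact engine state is attached as attribute `"engine"`.
#' @export
generate_lineage <- function(params) {
  stopifnot(inherits(params, "synth_lineage_params"))
  eng <- run_lineage_engine(params$n_founders, params$p_entry,
                            params$p_amp, params$p_spacing,
                            cap_mode = "truncate",
                            window_steps = params$max_steps,
                            line_max_rounds = Inf, seed = params$seed)
  rec <- engine_to_record(eng)
  attr(rec, "engine") <- eng
  rec
}
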