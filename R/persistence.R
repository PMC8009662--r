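# Post-division crescent persistence and normalized amplitude dynamics.

#' Construct a persistence trace
#'
#' Per-frame polarity records for one cell after an asymmetric division.
#' Frame 0 is the frame in which the new cell plate is first visible
#' (cytokinesis); frame times are minutes since then.
#'
#' @param cell_id Integer cell label.
#' @param frame_times Strictly increasing frame times in minutes, starting
#'   at 0.
#' @param records List of [polarity_record()] objects, one per frame (or a
#'   POME-table data frame with one row per frame in frame order).
#' @return An object of class `persistence_trace`.
#' @export
persistence_trace <- function(cell_id, frame_times, records) {
  if (is.data.frame(records)) {
    records <- lapply(seq_len(nrow(records)), function(i) {
      r <- records[i, ]
      structure(list(cell_id = r$cell_id, timepoint = r$timepoint,
                     bpi = r$bpi, crescent_fraction = r$crescent_fraction,
                     peak_height = r$peak_height,
                     fit = peak_fit(r$b, r$A, r$mu, r$sigma, r$rmse,
                                    r$converged)),
                class = "polarity_record")
    })
  }
  stopifnot(length(frame_times) == length(records),
            length(frame_times) >= 2L,
            frame_times[1] == 0, all(diff(frame_times) > 0))
  structure(list(cell_id = as.integer(cell_id),
                 frame_times = as.numeric(frame_times),
                 records = records),
            class = "persistence_trace")
}

#' @export
print.persistence_trace <- function(x, ...) {
  cat("<persistence_trace> cell", x$cell_id, "|",
      length(x$frame_times), "frames over",
      max(x$frame_times), "min\n")
  invisible(x)
}

# Amplitudes, baselines and fit rmse per frame.
trace_fits <- function(trace) {
  list(A = vapply(trace$records, function(r) r$fit$A, numeric(1)),
       b = vapply(trace$records, function(r) r$fit$b, numeric(1)),
       rmse = vapply(trace$records, function(r) r$fit$rmse, numeric(1)),
       sigma = vapply(trace$records, function(r) r$fit$sigma, numeric(1)),
       degenerate = vapply(trace$records,
                           function(r) isTRUE(r$fit$degenerate),
                           logical(1)))
}

# Width at which the fitted bump's FWHM reaches the full circle
# (2 * sigma * sqrt(2 log 2) = 2 * pi): beyond this the "bump" spans the
# whole circumference and is a baseline offset, not a polar crescent.
SIGMA_FULL_CIRCLE <- pi / sqrt(2 * log(2))

#' Measure crescent persistence from a trace
#'
#' Operationalizes "no longer visually detectable" as a rule on the
#' per-frame peak fits: a frame is detectable iff the fitted contrast
#' `A / b` is at least `detect_contrast` AND the fitted amplitude is at
#' least `detect_snr` times the fit's residual RMSE AND the fitted bump is
#' actually a crescent, i.e. its full width at half maximum is narrower
#' than the full circumference (near-flat profiles admit a degenerate
#' wide-bump/baseline reparameterization that the last condition rejects).
#' Persistence is the time of the first non-detectable frame; if every
#' frame is detectable the result is censored at the last frame time.
#'
#' @param trace A [persistence_trace()].
#' @param detect_contrast Minimum fitted amplitude-to-baseline ratio
#'   (default 0.2).
#' @param detect_snr Minimum fitted amplitude in units of residual RMSE
#'   (default 2.0).
#' @return An object of class `persistence_result`: list with `cell_id`,
#'   `persistence_minutes`, `end_frame` (0-based index of the first
#'   non-detectable frame, or the last frame if censored), `censored`,
#'   and `zero_at_start` (TRUE with a warning when frame 0 itself is not
#'   detectable).
#' @export
measure_persistence <- function(trace, detect_contrast = 0.2,
                                detect_snr = 2.0) {
  stopifnot(inherits(trace, "persistence_trace"))
  f <- trace_fits(trace)
  contrast <- ifelse(f$b > 0, f$A / f$b, Inf)
  detectable <- (contrast >= detect_contrast) &
    (f$A >= detect_snr * f$rmse) &
    (f$sigma < SIGMA_FULL_CIRCLE) & !f$degenerate

  if (!detectable[1]) {
    warning("crescent not detectable at frame 0 (cell ", trace$cell_id,
            "); zero-persistence result")
    return(structure(list(cell_id = trace$cell_id, persistence_minutes = 0,
                          end_frame = 0L, censored = FALSE,
                          zero_at_start = TRUE),
                     class = "persistence_result"))
  }
  first_gone <- which(!detectable)[1]
  if (is.na(first_gone)) {
    res <- list(cell_id = trace$cell_id,
                persistence_minutes = trace$frame_times[length(trace$frame_times)],
                end_frame = length(trace$frame_times) - 1L,
                censored = TRUE, zero_at_start = FALSE)
  } else {
    res <- list(cell_id = trace$cell_id,
                persistence_minutes = trace$frame_times[first_gone],
                end_frame = first_gone - 1L,
                censored = FALSE, zero_at_start = FALSE)
  }
  structure(res, class = "persistence_result")
}

#' @export
print.persistence_result <- function(x, ...) {
  cat("<persistence_result> cell", x$cell_id, "|",
      x$persistence_minutes, "min",
      if (x$censored) "(censored at last frame)" else "", "\n")
  invisible(x)
}

#' Normalized crescent amplitude curve
#'
#' The fitted peak amplitude of each frame divided by the amplitude at
#' timepoint 0, so the curve starts at exactly 1.
#'
#' @param trace A [persistence_trace()].
#' @return Numeric vector of per-frame fractions, same length as
#'   `trace$frame_times`.
#' @export
normalized_amplitude_curve <- function(trace) {
  stopifnot(inherits(trace, "persistence_trace"))
  A <- trace_fits(trace)$A
  if (A[1] <= 0) {
    stop("normalization undefined: fitted amplitude at timepoint 0 is zero")
  }
  A / A[1]
}

#' Compare persistence between two groups
#'
#' Difference of group mean persistence (censored traces excluded from the
#' means, their counts reported) and a two-sided Wilcoxon rank-sum p-value
#' on the uncensored persistence times.
#'
#' @param group_a,group_b Lists of [measure_persistence()] results.
#' @return A list with `mean_difference_minutes` (mean A minus mean B),
#'   `p_value`, `n_a`, `n_b` (uncensored counts), and `censored_a`,
#'   `censored_b`.
#' @export
compare_persistence_groups <- function(group_a, group_b) {
  pa <- vapply(group_a, `[[`, numeric(1), "persistence_minutes")
  pb <- vapply(group_b, `[[`, numeric(1), "persistence_minutes")
  ca <- vapply(group_a, `[[`, logical(1), "censored")
  cb <- vapply(group_b, `[[`, logical(1), "censored")
  ua <- pa[!ca]; ub <- pb[!cb]
  if (length(ua) < 3L || length(ub) < 3L) {
    stop("need at least 3 uncensored persistence results per group")
  }
  wt <- suppressWarnings(stats::wilcox.test(ua, ub, exact = FALSE))
  list(mean_difference_minutes = mean(ua) - mean(ub),
       p_value = wt$p.value,
       n_a = length(ua), n_b = length(ub),
       censored_a = sum(ca), censored_b = sum(cb))
}

#' Build persistence traces from POME tables and a track file
#'
#' Joins per-frame polarity measurements with a track table giving, for
#' each cell, the frame order and minutes since cytokinesis.
#'
#' @param pome A POME table (as from [measure_polarity()], possibly row-bound
#'   across frames) whose `timepoint` column matches `tracks$frame`.
#' @param tracks Data frame with columns `cell_id`, `frame`, `minutes`.
#' @return Named list of [persistence_trace()] objects, one per cell.
#' @export
build_persistence_traces <- function(pome, tracks) {
  stopifnot(all(c("cell_id", "frame", "minutes") %in% names(tracks)))
  out <- list()
  for (id in sort(unique(tracks$cell_id))) {
    tr <- tracks[tracks$cell_id == id, ]
    tr <- tr[order(tr$minutes), ]
    rows <- pome[pome$cell_id == id, ]
    rows <- rows[match(tr$frame, rows$timepoint), ]
    if (any(is.na(rows$cell_id))) {
      stop("missing POME rows for cell ", id, " at some tracked frames")
    }
    out[[as.character(id)]] <-
      persistence_trace(id, tr$minutes - tr$minutes[1], rows)
  }
  out
}
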