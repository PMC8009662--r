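# Polarity index and crescent metrics.

#' Compute the polarity index of a cortical profile
#'
#' The polarity index is the fraction of the measured portions whose
#' reporter intensity is at or above half of the per-cell maximum. A value
#' of 1 corresponds to a completely depolarized cortical signal (every
#' portion at least half the maximum); the smallest possible value for an
#' n-portion profile is `1/n` (only the maximal portion above half-max).
#' The at-or-above convention makes a perfectly uniform profile score
#' exactly 1.
#'
#' @param profile A [cortical_profile()], or a bare numeric vector of
#'   portion intensities.
#' @return The polarity index, a fraction in `[1/n, 1]`.
#' @export
compute_bpi <- function(profile) {
  v <- if (inherits(profile, "cortical_profile")) profile$reporter else profile
  stopifnot(is.numeric(v), length(v) >= 1L)
  m <- max(v)
  if (m <= 0) {
    stop("polarity index undefined: all portion intensities are zero")
  }
  sum(v >= m / 2) / length(v)
}

#' Select the brightest cells by mean reporter intensity
#'
#' Ranks profiles by their mean reporter intensity over all portions
#' (descending) and returns the top `k` cell ids; ties are broken by
#' ascending `cell_id`. This reproduces the convention of measuring the 10
#' brightest reporter-expressing cells per image.
#'
#' @param profiles List of [cortical_profile()] objects.
#' @param k Number of cells to select (default 10); if fewer profiles are
#'   given, all are returned.
#' @return Integer vector of selected cell ids, brightest first.
#' @export
select_brightest_cells <- function(profiles, k = 10L) {
  stopifnot(length(profiles) >= 1L)
  ids <- vapply(profiles, function(p) p$cell_id, integer(1))
  means <- vapply(profiles, function(p) mean(p$reporter), numeric(1))
  ord <- order(-means, ids)
  ids[ord][seq_len(min(k, length(ids)))]
}

#' Crescent size and peak height from a fitted peak
#'
#' The crescent fraction is the full width at half maximum of the fitted
#' bump, `2 * sigma * sqrt(2 * log(2))` radians, expressed as a fraction of
#' the full circle and capped at 1; the peak height is the fitted amplitude.
#' A zero-amplitude fit has no crescent (fraction 0).
#'
#' @param fit A [fit_peak()] result (`peak_fit`).
#' @return A list with `crescent_fraction` (fraction of perimeter in
#'   `[0, 1]`) and `peak_height` (AU).
#' @export
crescent_metrics <- function(fit) {
  stopifnot(inherits(fit, "peak_fit"))
  if (fit$A <= 0) {
    return(list(crescent_fraction = 0, peak_height = 0))
  }
  fwhm <- 2 * fit$sigma * sqrt(2 * log(2))
  list(crescent_fraction = min(fwhm / (2 * pi), 1), peak_height = fit$A)
}

#' Full polarity measurement of one profile
#'
#' Bundles the polarity index, the peak fit, and the crescent metrics for
#' one cell at one timepoint into a single record (one row of the POME
#' table).
#'
#' @param profile A [cortical_profile()].
#' @return An object of class `polarity_record`: a list with `cell_id`,
#'   `timepoint`, `bpi`, `crescent_fraction`, `peak_height`, and `fit`.
#' @export
polarity_record <- function(profile) {
  stopifnot(inherits(profile, "cortical_profile"))
  fit <- fit_peak(profile)
  cm <- crescent_metrics(fit)
  structure(list(cell_id = profile$cell_id, timepoint = profile$timepoint,
                 bpi = compute_bpi(profile),
                 crescent_fraction = cm$crescent_fraction,
                 peak_height = cm$peak_height, fit = fit),
            class = "polarity_record")
}

#' @export
print.polarity_record <- function(x, ...) {
  cat("<polarity_record> cell", x$cell_id, "t =", format(x$timepoint),
      "| BPI", round(x$bpi, 3), "| crescent",
      round(x$crescent_fraction, 3), "| peak height",
      round(x$peak_height, 2), "AU\n")
  invisible(x)
}

#' Measure polarity for the brightest cells of an image
#'
#' End-to-end measurement for one two-channel image with a label mask:
#' traces each cell outline, samples its cortical profile, keeps the
#' `top_k` brightest cells, and returns one POME-table row per kept cell.
#' Cells that cannot be traced (border-touching, holes, multi-component)
#' are skipped and reported in the `skipped` attribute.
#'
#' @param image Numeric array `c(h, w, 2)` (reporter, membrane).
#' @param mask Integer label matrix.
#' @param n_portions Portions per profile (default 63).
#' @param band_width Band width in pixels (default 3).
#' @param top_k Number of brightest cells to keep (default 10).
#' @param timepoint Timepoint label for the output rows.
#' @return A data frame (the POME table) with columns `cell_id`,
#'   `timepoint`, `bpi`, `crescent_fraction`, `peak_height`, `b`, `A`,
#'   `mu`, `sigma`, `rmse`, `converged`; attribute `skipped` lists
#'   untraceable cell ids with reasons.
#' @export
measure_polarity <- function(image, mask, n_portions = 63L, band_width = 3,
                             top_k = 10L, timepoint = 0) {
  ids <- mask_labels(mask)
  if (length(ids) == 0L) stop("mask contains no labeled cells")
  profiles <- list()
  skipped <- character(0)
  for (id in ids) {
    pr <- tryCatch({
      ol <- trace_outline(mask, id)
      sample_profile(image, ol, n_portions = n_portions,
                     band_width = band_width, timepoint = timepoint)
    }, error = function(e) conditionMessage(e))
    if (is.character(pr)) {
      skipped[as.character(id)] <- pr
    } else {
      profiles[[length(profiles) + 1L]] <- pr
    }
  }
  if (length(profiles) == 0L) stop("no measurable cells in mask")
  keep <- select_brightest_cells(profiles, k = top_k)
  rows <- lapply(profiles[match(keep, vapply(profiles, `[[`, integer(1),
                                             "cell_id"))],
                 function(p) as.data.frame(polarity_record(p)))
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  out
}

#' @export
as.data.frame.polarity_record <- function(x, ...) {
  data.frame(cell_id = x$cell_id, timepoint = x$timepoint, bpi = x$bpi,
             crescent_fraction = x$crescent_fraction,
             peak_height = x$peak_height,
             b = x$fit$b, A = x$fit$A, mu = x$fit$mu, sigma = x$fit$sigma,
             rmse = x$fit$rmse, converged = x$fit$converged)
}
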