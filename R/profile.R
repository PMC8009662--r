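# Cortical intensity profiles: the 63-portion measurement around a cell.

#' Construct a cortical profile
#'
#' Holds the per-portion reporter and membrane intensities measured around
#' one cell at one timepoint, with each portion located both by its angle
#' about the centroid and by its arc fraction along the outline.
#'
#' @param cell_id Integer cell label.
#' @param timepoint Timepoint label (numeric or character).
#' @param angle Portion midpoint angles, radians in `[0, 2*pi)`.
#' @param arc_fraction Portion midpoints as fraction of perimeter, strictly
#'   increasing in `[0, 1)`.
#' @param reporter,membrane Non-negative per-portion mean intensities, AU.
#' @return An object of class `cortical_profile`.
#' @export
cortical_profile <- function(cell_id, timepoint, angle, arc_fraction,
                             reporter, membrane) {
  n <- length(reporter)
  stopifnot(n >= 8L, length(membrane) == n, length(angle) == n,
            length(arc_fraction) == n,
            all(reporter >= 0), all(membrane >= 0),
            all(diff(arc_fraction) > 0),
            all(arc_fraction >= 0), all(arc_fraction < 1))
  structure(list(cell_id = as.integer(cell_id), timepoint = timepoint,
                 n_portions = n, angle = wrap_angle(angle),
                 arc_fraction = arc_fraction,
                 reporter = as.numeric(reporter),
                 membrane = as.numeric(membrane)),
            class = "cortical_profile")
}

#' @export
print.cortical_profile <- function(x, ...) {
  cat("<cortical_profile> cell", x$cell_id, "t =", format(x$timepoint),
      "|", x$n_portions, "portions | reporter mean",
      round(mean(x$reporter), 2), "AU\n")
  invisible(x)
}

# Vectorized bilinear interpolation of a matrix image at continuous
# (x, y) positions (0-based pixel-centre coordinates). Positions must lie
# inside [0, w-1] x [0, h-1].
bilinear_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x0 <- pmin(pmax(floor(x), 0), w - 2)
  y0 <- pmin(pmax(floor(y), 0), h - 2)
  fx <- x - x0
  fy <- y - y0
  i00 <- y0 + 1 + x0 * h          # column-major linear index of [y0+1, x0+1]
  i10 <- i00 + h                  # x0+1 -> next column
  i01 <- i00 + 1                  # y0+1 -> next row
  i11 <- i10 + 1
  img[i00] * (1 - fx) * (1 - fy) + img[i10] * fx * (1 - fy) +
    img[i01] * (1 - fx) * fy + img[i11] * fx * fy
}

# Resample a closed polygon at (approximately) equal arc-length spacing.
# Returns positions, unit normals and per-point arc fractions.
resample_boundary <- function(outline, step = 0.25) {
  x <- c(outline$x, outline$x[1])
  y <- c(outline$y, outline$y[1])
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  n_pts <- max(63L * 4L, ceiling(total / step))
  s <- (seq_len(n_pts) - 0.5) / n_pts * total
  sx <- stats::approx(cum, x, xout = s)$y
  sy <- stats::approx(cum, y, xout = s)$y
  # tangents by central differences on the resampled (uniform-s) loop
  tx <- (c(sx[-1], sx[1]) - c(sx[n_pts], sx[-n_pts])) / 2
  ty <- (c(sy[-1], sy[1]) - c(sy[n_pts], sy[-n_pts])) / 2
  tl <- sqrt(tx^2 + ty^2)
  list(x = sx, y = sy, nx = -ty / tl, ny = tx / tl,
       arc_fraction = s / total, total = total)
}

#' Sample the 63-portion cortical profile of one cell
#'
#' Splits the outline into `n_portions` equal arc-length portions and
#' measures, for each portion and channel, the mean intensity within a band
#' of width `band_width` centred on the boundary. The band mean is computed
#' by bilinear-interpolated quadrature over a dense grid of (arc position x
#' normal offset) sample points, which is insensitive to how pixels straddle
#' the band edge.
#'
#' @param image Numeric array `c(h, w, 2)` (channel 1 reporter, channel 2
#'   membrane) as produced by [render_cell_image()], or a single-channel
#'   matrix (then used for both channels).
#' @param outline A [cell_outline()].
#' @param n_portions Number of portions (default 63).
#' @param band_width Band width in pixels (default 3).
#' @param timepoint Timepoint label stored in the profile.
#' @return A [cortical_profile()].
#' @export
sample_profile <- function(image, outline, n_portions = 63L, band_width = 3,
                           timepoint = 0) {
  stopifnot(inherits(outline, "cell_outline"), n_portions >= 8L,
            band_width > 0)
  if (is.matrix(image)) {
    image <- array(rep(image, 2), dim = c(dim(image), 2))
  }
  stopifnot(length(dim(image)) == 3L, dim(image)[3] >= 2L)
  h <- dim(image)[1]; w <- dim(image)[2]

  rb <- resample_boundary(outline)
  n_off <- max(5L, 2L * ceiling(band_width) + 1L)
  offs <- seq(-band_width / 2, band_width / 2, length.out = n_off)

  n_pts <- length(rb$x)
  xx <- rep(rb$x, times = n_off) + rep(offs, each = n_pts) * rep(rb$nx, times = n_off)
  yy <- rep(rb$y, times = n_off) + rep(offs, each = n_pts) * rep(rb$ny, times = n_off)
  if (any(xx < 0 | xx > w - 1 | yy < 0 | yy > h - 1)) {
    stop("measurement band exits the image for cell ", outline$cell_id)
  }
  portion <- pmin(floor(rb$arc_fraction * n_portions) + 1L, n_portions)
  portion_all <- rep(portion, times = n_off)

  rep_vals <- bilinear_sample(image[, , 1], xx, yy)
  mem_vals <- bilinear_sample(image[, , 2], xx, yy)
  rep_mean <- as.numeric(tapply(rep_vals, portion_all, mean))
  mem_mean <- as.numeric(tapply(mem_vals, portion_all, mean))

  # portion midpoints: arc fraction and angle about the centroid
  mid_fr <- (seq_len(n_portions) - 0.5) / n_portions
  mid_idx <- pmin(pmax(round(mid_fr * n_pts + 0.5), 1L), n_pts)
  ang <- wrap_angle(atan2(rb$y[mid_idx] - outline$centroid[2],
                          rb$x[mid_idx] - outline$centroid[1]))
  cortical_profile(cell_id = outline$cell_id, timepoint = timepoint,
                   angle = ang, arc_fraction = mid_fr,
                   reporter = pmax(rep_mean, 0),
                   membrane = pmax(mem_mean, 0))
}
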