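# Synthetic two-channel cell renderer.
#
# Images are numeric arrays dim c(height, width, 2) in AU, channel 1 =
# reporter, channel 2 = membrane; pixel (ix, iy) (0-based, x right, y down)
# lives at [iy + 1, ix + 1, ]. Masks are integer matrices (0 = background).

# Outline radius at angle phi for a jittered ellipse centred at the image
# centre. coef: 3x2 matrix of harmonic coefficients (k = 2..4).
radius_function <- function(axes, jitter, coef) {
  force(axes); force(jitter); force(coef)
  function(phi) {
    a <- axes[1]; b <- axes[2]
    r <- a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
    if (jitter > 0) {
      j <- 0
      for (k in 2:4) {
        j <- j + coef[k - 1, 1] * cos(k * phi) + coef[k - 1, 2] * sin(k * phi)
      }
      r <- r * (1 + jitter * j / 3)
    }
    r
  }
}

# Draw the outline-jitter harmonic coefficients for a cell (consumes RNG).
draw_jitter_coef <- function() {
  matrix(stats::runif(6, -1, 1), nrow = 3, ncol = 2)
}

#' Render a synthetic two-channel cell image
#'
#' Paints a uniform membrane band along a jittered-ellipse outline and a
#' reporter band carrying `baseline + amplitude * wrapped_gaussian(...)`
#' evaluated at the angular position of each band pixel, 4x supersampled,
#' with i.i.d. Gaussian noise truncated at zero added to the reporter
#' channel. Rendering is byte-identical for identical parameters and seed.
#'
#' @param params A [synth_cell_params()] object.
#' @return A list with elements:
#'   \describe{
#'     \item{image}{numeric array `c(h, w, 2)`; channel 1 reporter,
#'       channel 2 membrane, AU.}
#'     \item{mask}{integer matrix `c(h, w)`; `cell_id` inside the cell,
#'       0 outside.}
#'     \item{truth}{ground-truth record: all generator parameters plus the
#'       outline polygon, perimeter, area, and `periphery_fraction`, the
#'       fraction of boundary arc where the noise-free bump exceeds half its
#'       own maximum.}
#'   }
#' @export
render_cell_image <- function(params) {
  stopifnot(inherits(params, "synth_cell_params"))
  h <- params$image_size[1]; w <- params$image_size[2]
  cx <- (w - 1) / 2; cy <- (h - 1) / 2

  set.seed(params$seed)
  coef <- draw_jitter_coef()
  rfun <- radius_function(params$axes, params$jitter, coef)

  # sizing check against the image border
  phis <- seq(0, 2 * pi, length.out = 721L)[-721L]
  rmax <- max(rfun(phis))
  margin <- params$band_width / 2 + params$feather + 1
  if (rmax + margin >= min(cx, cy, (w - 1) - cx, (h - 1) - cy)) {
    stop("cell outline (radius ", round(rmax, 1),
         " px + band) exceeds image bounds; enlarge `image_size`")
  }

  half_band <- params$band_width / 2 + params$feather
  xs <- 0:(w - 1); ys <- 0:(h - 1)
  px <- matrix(xs, nrow = h, ncol = w, byrow = TRUE)
  py <- matrix(ys, nrow = h, ncol = w)

  rep_ch <- matrix(0, h, w)
  mem_ch <- matrix(0, h, w)
  ss <- 4L
  off <- ((seq_len(ss) - 0.5) / ss) - 0.5
  for (oy in off) {
    for (ox in off) {
      dx <- px + ox - cx
      dy <- py + oy - cy
      phi <- atan2(dy, dx)
      rho <- sqrt(dx^2 + dy^2)
      inband <- abs(rho - rfun(phi)) <= half_band
      val <- params$baseline
      if (params$amplitude > 0) {
        val <- val + params$amplitude *
          wrapped_gaussian(angle_diff(phi, params$center), params$sigma)
      }
      rep_ch <- rep_ch + inband * val
      mem_ch <- mem_ch + inband * params$membrane_level
    }
  }
  rep_ch <- rep_ch / ss^2
  mem_ch <- mem_ch / ss^2

  if (params$noise_sd > 0) {
    rep_ch <- pmax(0, rep_ch + matrix(stats::rnorm(h * w, 0, params$noise_sd), h, w))
  }

  dxm <- px - cx; dym <- py - cy
  phim <- atan2(dym, dxm)
  mask <- matrix(0L, h, w)
  mask[sqrt(dxm^2 + dym^2) <= rfun(phim)] <- params$cell_id

  # ground-truth boundary polygon (fine angular sampling)
  bx <- cx + rfun(phis) * cos(phis)
  by <- cy + rfun(phis) * sin(phis)
  seg <- sqrt(diff(c(bx, bx[1]))^2 + diff(c(by, by[1]))^2)
  perim <- sum(seg)
  area <- polygon_area(bx, by)
  if (params$amplitude > 0) {
    # finer angular grid for the arc-fraction ground truth
    phif <- seq(0, 2 * pi, length.out = 14401L)[-14401L]
    bxf <- cx + rfun(phif) * cos(phif)
    byf <- cy + rfun(phif) * sin(phif)
    segf <- sqrt(diff(c(bxf, bxf[1]))^2 + diff(c(byf, byf[1]))^2)
    above <- wrapped_gaussian(angle_diff(phif, params$center),
                              params$sigma) >= 0.5
    periphery_fraction <- sum(segf[above]) / sum(segf)
  } else {
    periphery_fraction <- 0
  }

  image <- array(0, dim = c(h, w, 2))
  image[, , 1] <- rep_ch
  image[, , 2] <- mem_ch
  truth <- c(unclass(params),
             list(boundary_x = bx, boundary_y = by,
                  centroid = c(cx, cy), perimeter = perim, area = area,
                  ellipse_area = pi * params$axes[1] * params$axes[2],
                  periphery_fraction = periphery_fraction))
  list(image = image, mask = mask, truth = truth)
}

#' Generate a cortical profile directly from the crescent model
#'
#' Profile-level counterpart of [render_cell_image()]: evaluates
#' `baseline + amplitude * wrapped_gaussian(...)` at the `n_portions` portion
#' midpoints of an idealized circular cell and adds truncated Gaussian noise
#' per portion. Fast path for simulation studies that do not need pixels.
#'
#' @param params A [synth_cell_params()] object (outline fields are ignored
#'   except for reporting; `noise_sd` applies per portion).
#' @param n_portions Number of portions (default 63).
#' @param timepoint Timepoint label stored in the profile.
#' @return A [cortical_profile()] object.
#' @export
synth_profile <- function(params, n_portions = 63L, timepoint = 0) {
  stopifnot(inherits(params, "synth_cell_params"))
  set.seed(params$seed)
  theta <- portion_midpoints(n_portions)
  rep_v <- rep(params$baseline, n_portions)
  if (params$amplitude > 0) {
    rep_v <- rep_v + params$amplitude *
      wrapped_gaussian(angle_diff(theta, params$center), params$sigma)
  }
  if (params$noise_sd > 0) {
    rep_v <- pmax(0, rep_v + stats::rnorm(n_portions, 0, params$noise_sd))
  }
  cortical_profile(cell_id = params$cell_id, timepoint = timepoint,
                   angle = theta, arc_fraction = (seq_len(n_portions) - 0.5) / n_portions,
                   reporter = rep_v,
                   membrane = rep(params$membrane_level, n_portions))
}

#' Render a synthetic post-division time series
#'
#' Renders one frame per timepoint with the crescent amplitude following the
#' decay law of [true_amplitude()]; all other cell parameters are shared.
#' Frame `f` uses the deterministic child seed `cell$seed + f + 1`.
#'
#' @param series A [synth_series_params()] object.
#' @param cell A [synth_cell_params()] object (its `amplitude` is replaced
#'   frame by frame; its `seed` seeds the per-frame child streams).
#' @return A list with `frames` (list of [render_cell_image()] results),
#'   `frame_times` (minutes), and `truth` containing `true_amplitude` per
#'   frame and `first_zero_frame` (0-based index of the first frame with zero
#'   true amplitude, or `NA` if none).
#' @export
render_time_series <- function(series, cell) {
  stopifnot(inherits(series, "synth_series_params"),
            inherits(cell, "synth_cell_params"))
  times <- (seq_len(series$n_frames) - 1L) * series$frame_interval
  amps <- true_amplitude(series, times)
  amps[amps > 0 & amps / series$amplitude < 1e-9] <- 0  # numerically dead
  frames <- vector("list", series$n_frames)
  for (f in seq_len(series$n_frames)) {
    p <- cell
    p$amplitude <- amps[f]
    p$seed <- cell$seed + f
    frames[[f]] <- render_cell_image(p)
  }
  fz <- which(amps == 0)
  list(frames = frames, frame_times = times,
       truth = list(true_amplitude = amps,
                    first_zero_frame = if (length(fz)) fz[1] - 1L else NA_integer_,
                    disappearance_time = series$disappearance_time,
                    half_life = series$half_life))
}

#' Generate a profile-level post-division time series
#'
#' Profile-level counterpart of [render_time_series()]: one
#' [cortical_profile()] per frame, generated by [synth_profile()] with the
#' decayed amplitude, using child seed `cell$seed + f + 1` for frame `f`.
#'
#' @inheritParams render_time_series
#' @return A list with `profiles` (list of [cortical_profile()]),
#'   `frame_times`, and the same `truth` as [render_time_series()].
#' @export
synth_profile_series <- function(series, cell) {
  stopifnot(inherits(series, "synth_series_params"),
            inherits(cell, "synth_cell_params"))
  times <- (seq_len(series$n_frames) - 1L) * series$frame_interval
  amps <- true_amplitude(series, times)
  profiles <- vector("list", series$n_frames)
  for (f in seq_len(series$n_frames)) {
    p <- cell
    p$amplitude <- amps[f]
    p$seed <- cell$seed + f
    profiles[[f]] <- synth_profile(p, timepoint = times[f])
  }
  fz <- which(amps == 0)
  list(profiles = profiles, frame_times = times,
       truth = list(true_amplitude = amps,
                    first_zero_frame = if (length(fz)) fz[1] - 1L else NA_integer_,
                    disappearance_time = series$disappearance_time,
                    half_life = series$half_life))
}

#' Generate a randomized suite of synthetic cortical profiles
#'
#' Draws `n` profiles spanning polarized, depolarized and noisy regimes:
#' amplitude uniform on [0, 120] AU (with a fifth of the cells forced to
#' amplitude 0, i.e. fully depolarized), baseline uniform on [1, 30] AU,
#' width uniform on [0.1, 2] rad, center uniform on the circle, and noise
#' s.d. uniform on [0, 15] AU. Deterministic given the master seed; profile
#' `i` renders with child seed `seed + 10000 + i`.
#'
#' @param n Number of profiles.
#' @param seed Master seed.
#' @param n_portions Portions per profile (default 63).
#' @return List of [cortical_profile()] objects.
#' @export
synth_profile_suite <- function(n = 1000L, seed = 1L, n_portions = 63L) {
  set.seed(seed)
  amp <- stats::runif(n, 0, 120)
  amp[seq_len(n) %% 5L == 0L] <- 0
  base <- stats::runif(n, 1, 30)
  sig <- stats::runif(n, 0.1, 2)
  ctr <- stats::runif(n, 0, 2 * pi)
  nsd <- stats::runif(n, 0, 15)
  lapply(seq_len(n), function(i) {
    synth_profile(synth_cell_params(amplitude = amp[i], baseline = base[i],
                                    sigma = sig[i], center = ctr[i],
                                    noise_sd = nsd[i], cell_id = i,
                                    seed = seed + 10000L + i),
                  n_portions = n_portions)
  })
}
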