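#' Parameters for a synthetic polarized cell image
#'
#' Describes one synthetic epidermal cell: a jittered-ellipse outline, a
#' uniform membrane band, and a reporter channel carrying a constant cortical
#' baseline plus a wrapped-Gaussian crescent, with additive truncated-Gaussian
#' noise. All intensities are in arbitrary units (AU) on the same scale as the
#' rendered 16-bit images.
#'
#' @param axes Ellipse semi-axes in pixels, length 2.
#' @param jitter Relative amplitude of low-order harmonic jitter applied to
#'   the outline radius (0 = exact ellipse).
#' @param band_width Nominal cortical band width in pixels. The renderer
#'   paints the band with an extra `feather` margin so that the nominal band
#'   is photometrically flat at the sampling stage.
#' @param baseline Cortical baseline intensity of the reporter, AU, `>= 0`.
#' @param amplitude Crescent peak height above baseline, AU, `>= 0`.
#' @param center Crescent center, radians in `[0, 2*pi)`.
#' @param sigma Crescent width (wrapped-Gaussian sigma), radians; must be
#'   `> 0` whenever `amplitude > 0`.
#' @param noise_sd Standard deviation of additive Gaussian noise (truncated
#'   at 0) on the reporter channel, AU, `>= 0`.
#' @param membrane_level Uniform membrane-band intensity, AU.
#' @param image_size Image height and width in pixels, length 2.
#' @param feather Extra painted band margin in pixels (anti-alias guard).
#' @param cell_id Integer label written into the mask.
#' @param seed Integer seed; rendering is deterministic given the seed.
#' @return An object of class `synth_cell_params` (a validated list).
#' @export
synth_cell_params <- function(axes = c(22, 16), jitter = 0.04,
                              band_width = 3, baseline = 10,
                              amplitude = 90, center = pi / 2,
                              sigma = 0.3, noise_sd = 5,
                              membrane_level = 100,
                              image_size = c(96L, 96L),
                              feather = 2, cell_id = 1L, seed = 1L) {
  p <- list(axes = as.numeric(axes), jitter = as.numeric(jitter),
            band_width = as.numeric(band_width),
            baseline = as.numeric(baseline),
            amplitude = as.numeric(amplitude),
            center = wrap_angle(as.numeric(center)),
            sigma = as.numeric(sigma), noise_sd = as.numeric(noise_sd),
            membrane_level = as.numeric(membrane_level),
            image_size = as.integer(image_size),
            feather = as.numeric(feather),
            cell_id = as.integer(cell_id), seed = as.integer(seed))
  stopifnot(length(p$axes) == 2L, all(p$axes > 0),
            p$jitter >= 0, p$band_width > 0,
            p$baseline >= 0, p$amplitude >= 0, p$noise_sd >= 0,
            p$membrane_level > 0,
            length(p$image_size) == 2L, all(p$image_size >= 16L),
            p$feather >= 0, p$cell_id >= 1L,
            p$seed >= 0L, p$seed < 2^30)
  if (p$amplitude > 0 && !(p$sigma > 0)) {
    stop("`sigma` must be > 0 when `amplitude` > 0")
  }
  class(p) <- "synth_cell_params"
  p
}

#' Parameters for a synthetic post-division time series
#'
#' Describes the decay of a crescent after an asymmetric division: frames are
#' taken at a fixed interval (time-lapse cadence, default 40 min); the true
#' crescent amplitude follows an exponential half-life law and drops to zero
#' once `disappearance_time` is reached.
#'
#' @param frame_interval Minutes between frames, `> 0`.
#' @param n_frames Number of frames, `>= 2`; frame 0 is cytokinesis.
#' @param amplitude Initial crescent amplitude A(0), AU.
#' @param half_life Amplitude half-life in minutes (`Inf` for no decay).
#' @param disappearance_time Minutes after which the true amplitude is
#'   exactly 0 (may exceed the last frame time; use `Inf` for never).
#' @param seed Integer seed.
#' @return An object of class `synth_series_params`.
#' @export
synth_series_params <- function(frame_interval = 40, n_frames = 13L,
                                amplitude = 100, half_life = 480,
                                disappearance_time = 480, seed = 1L) {
  p <- list(frame_interval = as.numeric(frame_interval),
            n_frames = as.integer(n_frames),
            amplitude = as.numeric(amplitude),
            half_life = as.numeric(half_life),
            disappearance_time = as.numeric(disappearance_time),
            seed = as.integer(seed))
  stopifnot(p$frame_interval > 0, p$n_frames >= 2L,
            p$amplitude >= 0, p$half_life > 0,
            p$disappearance_time >= 0,
            p$seed >= 0L, p$seed < 2^30)
  class(p) <- "synth_series_params"
  p
}

#' True crescent amplitude at given times
#'
#' The generator's decay law: `A(t) = A0 * 2^(-t / half_life)` for
#' `t < disappearance_time`, and exactly 0 afterwards. Non-increasing in `t`.
#'
#' @param params A [synth_series_params()] object.
#' @param times Minutes since cytokinesis.
#' @return Numeric vector of true amplitudes.
#' @export
true_amplitude <- function(params, times) {
  stopifnot(inherits(params, "synth_series_params"))
  a <- params$amplitude * 2^(-times / params$half_life)
  a[times >= params$disappearance_time] <- 0
  a
}

#' Parameters for a synthetic lineage-tracing record
#'
#' Transition probabilities of the stomatal-lineage state machine used to
#' generate ground-truthed lineage records: protodermal founders enter via an
#' asymmetric entry division, meristemoids either self-renew (amplifying
#' division) or differentiate into a guard mother cell (GMC), SLGCs either
#' respace (spacing division) or become pavement cells, and each GMC divides
#' symmetrically into a guard-cell pair.
#'
#' @param n_founders Number of founder protodermal cells, `>= 1`.
#' @param p_entry Probability a founder enters the lineage (single decision).
#' @param p_amp Probability a meristemoid amplifies at each round.
#' @param p_spacing Probability an SLGC undergoes a spacing division.
#' @param max_steps Number of observation rounds in the tracing window.
#' @param seed Integer seed.
#' @return An object of class `synth_lineage_params`.
#' @export
synth_lineage_params <- function(n_founders = 100L, p_entry = 1,
                                 p_amp = 0.5, p_spacing = 0,
                                 max_steps = 8L, seed = 1L) {
  p <- list(n_founders = as.integer(n_founders),
            p_entry = as.numeric(p_entry), p_amp = as.numeric(p_amp),
            p_spacing = as.numeric(p_spacing),
            max_steps = as.integer(max_steps), seed = as.integer(seed))
  stopifnot(p$n_founders >= 1L,
            p$p_entry >= 0, p$p_entry <= 1,
            p$p_amp >= 0, p$p_amp <= 1,
            p$p_spacing >= 0, p$p_spacing <= 1,
            p$max_steps >= 1L, p$seed >= 0L, p$seed < 2^30)
  class(p) <- "synth_lineage_params"
  p
}
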