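#' Specification of a synthetic scene
#'
#' A `scene_spec` collects every knob of the synthetic video generators:
#' geometry and calibration, the intensity model and its parameters, the
#' log-log power-law slopes of the spatial and temporal amplitude spectra,
#' an optional top-bright/bottom-dark illumination ramp, and the RNG seed.
#' Identical specs (including the seed) produce bit-identical videos.
#'
#' The default geometry mirrors a 10-s field sample: 225 x 225 pixels at
#' 1/3 degree per pixel (a 75 x 75 degree window) and 1001 frames at
#' 100 frames/s. Tests use smaller sizes.
#'
#' @param width_px,height_px,n_frames Grid size; each must be >= 8.
#' @param deg_per_px Degrees per pixel (> 0). Default `1/3`.
#' @param frame_rate Frames per second (> 0). Default 100.
#' @param intensity_model One of `"gaussian"`, `"lognormal"`, `"two-level"`.
#' @param intensity_params Named list. For `"gaussian"`: `mean`, `sd`.
#'   For `"lognormal"`: `mean` (linear-scale mean) and `sigma_log`
#'   (log-scale standard deviation, > 0). For `"two-level"`: `low`, `high`,
#'   `p_low` (probability of the low level).
#' @param spatial_slope,temporal_slope Target log-log power-spectrum slopes
#'   in `[-5, 0]` used by [generate_powerlaw_video()].
#' @param gradient_amplitude Fractional top-to-bottom luminance change in
#'   `[0, 1)` used by [generate_gradient_scene()].
#' @param seed Integer RNG seed.
#'
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(width_px = 225L, height_px = 225L, n_frames = 1001L,
                       deg_per_px = 1 / 3, frame_rate = 100,
                       intensity_model = c("gaussian", "lognormal", "two-level"),
                       intensity_params = list(mean = 100, sd = 10),
                       spatial_slope = -2, temporal_slope = -1.5,
                       gradient_amplitude = 0, seed = 1L) {
  intensity_model <- match.arg(intensity_model)
  dims <- c(width_px = width_px, height_px = height_px, n_frames = n_frames)
  if (any(!is.finite(dims)) || any(dims < 8)) {
    stop("width_px, height_px and n_frames must all be >= 8", call. = FALSE)
  }
  if (deg_per_px <= 0 || frame_rate <= 0) {
    stop("deg_per_px and frame_rate must be positive", call. = FALSE)
  }
  if (spatial_slope < -5 || spatial_slope > 0 ||
      temporal_slope < -5 || temporal_slope > 0) {
    stop("spectral slopes must lie in [-5, 0]", call. = FALSE)
  }
  if (gradient_amplitude < 0 || gradient_amplitude >= 1) {
    stop("gradient_amplitude must lie in [0, 1)", call. = FALSE)
  }
  if (intensity_model == "lognormal") {
    s <- intensity_params$sigma_log
    if (is.null(s) || !is.finite(s) || s <= 0) {
      stop("lognormal model requires intensity_params$sigma_log > 0",
           call. = FALSE)
    }
  }
  if (intensity_model == "two-level") {
    p <- intensity_params$p_low
    if (is.null(p) || p < 0 || p > 1) {
      stop("two-level model requires intensity_params$p_low in [0, 1]",
           call. = FALSE)
    }
  }
  structure(
    list(
      width_px = as.integer(width_px),
      height_px = as.integer(height_px),
      n_frames = as.integer(n_frames),
      deg_per_px = deg_per_px,
      frame_rate = frame_rate,
      intensity_model = intensity_model,
      intensity_params = intensity_params,
      spatial_slope = spatial_slope,
      temporal_slope = temporal_slope,
      gradient_amplitude = gradient_amplitude,
      seed = as.integer(seed)
    ),
    class = "scene_spec"
  )
}

#' Specification of a moving-dot field
#'
#' Dots drift with per-dot speeds drawn from a parametric distribution and
#' wrap toroidally, so the dot count is conserved in every frame. Used to
#' test the iso-speed interpretation of the joint spatiotemporal spectrum:
#' a field drifting at speed v concentrates power on the locus
#' `f_t = v * f_s`.
#'
#' @param n_dots Number of dots (>= 1).
#' @param dot_diameter_deg Dot diameter in degrees. Dots smaller than one
#'   pixel are rendered as single pixels with a warning.
#' @param speed_family `"fixed"` (all dots at `speed_mean`) or `"gamma"`
#'   (shape/rate chosen to hit `speed_mean` and `speed_sd`).
#' @param speed_mean,speed_sd Speed distribution parameters, degrees/second.
#' @param direction `"uniform"` for random headings or a single angle in
#'   radians applied to all dots.
#' @param contrast_polarity `"bright"`, `"dark"`, or `"mixed"`.
#' @param seed Integer RNG seed.
#'
#' @return An object of class `dot_field_spec`.
#' @export
dot_field_spec <- function(n_dots = 20L, dot_diameter_deg = 2,
                           speed_family = c("fixed", "gamma"),
                           speed_mean = 10, speed_sd = 0,
                           direction = "uniform",
                           contrast_polarity = c("bright", "dark", "mixed"),
                           seed = 1L) {
  speed_family <- match.arg(speed_family)
  contrast_polarity <- match.arg(contrast_polarity)
  if (n_dots < 1) stop("n_dots must be >= 1", call. = FALSE)
  if (!is.finite(speed_mean) || speed_mean < 0) {
    stop("speed_mean must be finite and >= 0", call. = FALSE)
  }
  if (speed_sd < 0) stop("speed_sd must be >= 0", call. = FALSE)
  structure(
    list(
      n_dots = as.integer(n_dots),
      dot_diameter_deg = dot_diameter_deg,
      speed_family = speed_family,
      speed_mean = speed_mean,
      speed_sd = speed_sd,
      direction = direction,
      contrast_polarity = contrast_polarity,
      seed = as.integer(seed)
    ),
    class = "dot_field_spec"
  )
}
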