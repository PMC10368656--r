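#' Synthetic video generators
#'
#' These generators produce [video_sample()] blocks with known ground-truth
#' statistics so that every downstream stage (contrast, entropy, spectra,
#' nonlinearities, inference) can be validated without field recordings.
#' All of them are deterministic given their spec, including the seed.
#'
#' @name synthetic-data
NULL

# fft-order frequency axis in cycles per sample unit
fft_freqs <- function(n, d = 1) {
  k <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1))
  k / (n * d)
}

#' Generate a video with separable power-law spectra
#'
#' Builds a random field whose expected power spectrum is separable with
#' marginal log-log slopes equal to `spec$spatial_slope` (against radial
#' spatial frequency) and `spec$temporal_slope`. Construction: white
#' Gaussian noise is filtered in the Fourier domain by the real, even
#' amplitude `r^(slope_s/2) * |f_t|^(slope_t/2)` (zero at the zero-frequency
#' planes), inverse-transformed, and affine-mapped into the positive
#' luminance band `mean * [1 - a, 1 + a]` with `a = 0.9` so contrast
#' normalization by the mean is well-defined.
#'
#' @param spec A [scene_spec()]; slopes must lie in `[-5, 0]`.
#' @return A [video_sample()].
#' @export
generate_powerlaw_video <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  ny <- spec$height_px; nx <- spec$width_px; nt <- spec$n_frames
  fy <- fft_freqs(ny, spec$deg_per_px)
  fx <- fft_freqs(nx, spec$deg_per_px)
  ft <- fft_freqs(nt, 1 / spec$frame_rate)

  r <- sqrt(outer(fy^2, fx^2, `+`))          # ny x nx radial spatial freq
  amp_s <- ifelse(r > 0, r^(spec$spatial_slope / 2), 0)
  amp_t <- ifelse(abs(ft) > 0, abs(ft)^(spec$temporal_slope / 2), 0)
  amp <- outer(amp_s, amp_t)                  # ny x nx x nt
  dim(amp) <- c(ny, nx, nt)

  z <- withr::with_seed(spec$seed, {
    noise <- array(stats::rnorm(ny * nx * nt), dim = c(ny, nx, nt))
    Re(stats::fft(stats::fft(noise) * amp, inverse = TRUE)) / (ny * nx * nt)
  })

  m <- spec$intensity_params$mean %||% 100
  a <- 0.9
  z <- z - mean(z)
  peak <- max(abs(z))
  if (peak > 0) z <- z / peak
  intens <- m * (1 + a * z)
  video_sample(intens, spec$deg_per_px, spec$frame_rate, "synthetic")
}

#' Generate an i.i.d. intensity field with controlled distribution shape
#'
#' Draws every pixel-frame independently from the spec's intensity model.
#' The lognormal model emulates the positively skewed, leptokurtotic
#' intensity fields typical of natural scenes: its global-contrast skewness
#' has the closed form `(exp(s^2) + 2) * sqrt(exp(s^2) - 1)` for log-scale
#' standard deviation `s`, and more than half of all pixels fall below the
#' mean (dark dominance). The two-level model pins the proportion of
#' negative contrast exactly at `p_low`.
#'
#' @param spec A [scene_spec()].
#' @return A [video_sample()].
#' @export
generate_skewed_field <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  n <- spec$height_px * spec$width_px * spec$n_frames
  p <- spec$intensity_params
  vals <- withr::with_seed(spec$seed, {
    switch(spec$intensity_model,
      "gaussian" = pmax(stats::rnorm(n, p$mean %||% 100, p$sd %||% 10), 0),
      "lognormal" = stats::rlnorm(
        n,
        meanlog = log(p$mean %||% 100) - p$sigma_log^2 / 2,
        sdlog = p$sigma_log
      ),
      "two-level" = {
        lo <- p$low %||% 50
        hi <- p$high %||% 150
        ifelse(stats::runif(n) < p$p_low, lo, hi)
      }
    )
  })
  intens <- array(vals, dim = c(spec$height_px, spec$width_px, spec$n_frames))
  video_sample(intens, spec$deg_per_px, spec$frame_rate, "synthetic")
}

# row multipliers for the illumination ramp: top row (row 1) brightest
gradient_ramp <- function(height_px, amplitude) {
  if (height_px == 1L) return(1)
  1 + amplitude * (1 - 2 * (seq_len(height_px) - 1) / (height_px - 1))
}

#' Generate a scene with a vertical illumination gradient
#'
#' Multiplies a base intensity field (drawn from the spec's intensity
#' model) by a linear top-bright/bottom-dark ramp whose row multipliers run
#' from `1 + gradient_amplitude` at the top of the visual field to
#' `1 - gradient_amplitude` at the bottom (mean 1 across rows). This
#' emulates illumination from above: with a positive amplitude the upper
#' hemifield has positive mean global contrast and the lower hemifield
#' negative.
#'
#' @param spec A [scene_spec()]; `gradient_amplitude` in `[0, 1)`.
#' @param constant_base If `TRUE`, use a constant base at the model mean so
#'   the per-row contrast is an exact linear ramp.
#' @return A [video_sample()].
#' @export
generate_gradient_scene <- function(spec, constant_base = FALSE) {
  stopifnot(inherits(spec, "scene_spec"))
  if (constant_base) {
    m <- spec$intensity_params$mean %||% 100
    base <- array(m, dim = c(spec$height_px, spec$width_px, spec$n_frames))
  } else {
    base <- generate_skewed_field(spec)$intensities
  }
  ramp <- gradient_ramp(spec$height_px, spec$gradient_amplitude)
  intens <- base * ramp   # recycles down columns: row-wise multiplier
  video_sample(intens, spec$deg_per_px, spec$frame_rate, "synthetic")
}

#' Generate a moving-dot video
#'
#' Renders hard (un-anti-aliased) discs drifting over a uniform background
#' with toroidal wrap-around, so the number of dots is conserved in every
#' frame. Per-dot speeds come from the spec's speed distribution; with a
#' single fixed speed `v` the joint spatiotemporal spectrum concentrates
#' power along the iso-speed locus `f_t = v * f_s`.
#'
#' @param spec A [dot_field_spec()].
#' @param scene A [scene_spec()] supplying geometry, frame rate and mean
#'   luminance.
#' @return A [video_sample()].
#' @export
generate_dot_video <- function(spec, scene) {
  stopifnot(inherits(spec, "dot_field_spec"), inherits(scene, "scene_spec"))
  ny <- scene$height_px; nx <- scene$width_px; nt <- scene$n_frames
  m <- scene$intensity_params$mean %||% 100
  radius_px <- spec$dot_diameter_deg / scene$deg_per_px / 2
  if (radius_px < 0.5) {
    warning("dot diameter below one pixel; dots rendered as single pixels",
            call. = FALSE)
    radius_px <- 0.5
  }

  state <- withr::with_seed(spec$seed, {
    nd <- spec$n_dots
    speeds <- switch(spec$speed_family,
      "fixed" = rep(spec$speed_mean, nd),
      "gamma" = if (spec$speed_sd == 0) {
        rep(spec$speed_mean, nd)
      } else {
        shape <- (spec$speed_mean / spec$speed_sd)^2
        stats::rgamma(nd, shape = shape, rate = shape / spec$speed_mean)
      }
    )
    dirs <- if (identical(spec$direction, "uniform")) {
      stats::runif(nd, 0, 2 * pi)
    } else {
      rep(as.numeric(spec$direction), nd)
    }
    pol <- switch(spec$contrast_polarity,
      "bright" = rep(1, nd),
      "dark" = rep(-1, nd),
      "mixed" = sample(c(-1, 1), nd, replace = TRUE)
    )
    list(
      x0 = stats::runif(nd, 0, nx), y0 = stats::runif(nd, 0, ny),
      speeds = speeds, dirs = dirs, pol = pol
    )
  })

  px_per_frame <- state$speeds / scene$deg_per_px / scene$frame_rate
  dot_contrast <- 0.5
  xs <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  ys <- matrix(rep(seq_len(ny), nx), ny, nx)
  intens <- array(m, dim = c(ny, nx, nt))
  for (t in seq_len(nt)) {
    frame <- matrix(m, ny, nx)
    cx <- (state$x0 + px_per_frame * (t - 1) * cos(state$dirs)) %% nx
    cy <- (state$y0 + px_per_frame * (t - 1) * sin(state$dirs)) %% ny
    for (d in seq_along(cx)) {
      # toroidal distance to the disc centre
      dx <- abs(xs - 1 - cx[d]); dx <- pmin(dx, nx - dx)
      dy <- abs(ys - 1 - cy[d]); dy <- pmin(dy, ny - dy)
      hit <- (dx * dx + dy * dy) <= radius_px^2
      frame[hit] <- m * (1 + state$pol[d] * dot_contrast)
    }
    intens[, , t] <- frame
  }
  video_sample(intens, scene$deg_per_px, scene$frame_rate, "synthetic")
}

#' Write a sample as a PNG frame directory with a JSON sidecar
#'
#' Frames are quantized to 8-bit grayscale PNG files (`frame_000001.png`,
#' ...) spanning the sample's intensity range; the sidecar
#' (`sample_meta.json`) records the calibration needed to reconstruct
#' linear intensities on read: `deg_per_px`, `frame_rate`, the intensity
#' range, and the environment label. The result is readable by
#' [load_frames()] / [read_sample_frames()].
#'
#' @param sample A [video_sample()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sample_frames <- function(sample, dir) {
  stopifnot(inherits(sample, "video_sample"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rng <- range(sample$intensities)
  span <- if (diff(rng) > 0) diff(rng) else 1
  nt <- dim(sample$intensities)[3]
  for (t in seq_len(nt)) {
    frame <- (sample$intensities[, , t] - rng[1]) / span
    png::writePNG(frame, file.path(dir, sprintf("frame_%06d.png", t)),
                  dpi = NULL)
  }
  jsonlite::write_json(
    list(
      deg_per_px = sample$deg_per_px,
      frame_rate = sample$frame_rate,
      intensity_min = rng[1],
      intensity_max = rng[2],
      environment = sample$environment,
      n_frames = nt
    ),
    file.path(dir, "sample_meta.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a PNG frame directory written by [write_sample_frames()]
#'
#' @param dir Directory containing `frame_*.png` and `sample_meta.json`.
#' @return A [video_sample()].
#' @export
read_sample_frames <- function(dir) {
  meta_path <- file.path(dir, "sample_meta.json")
  if (!file.exists(meta_path)) {
    stop("no sample_meta.json sidecar in ", dir, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^frame_.*\\.png$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no frames found in ", dir, call. = FALSE)
  frames <- lapply(files, png::readPNG)
  d <- dim(frames[[1]])[1:2]
  intens <- array(0, dim = c(d[1], d[2], length(frames)))
  for (t in seq_along(frames)) {
    f <- frames[[t]]
    if (length(dim(f)) == 3) f <- f[, , 2]   # green channel of RGB frames
    intens[, , t] <- f
  }
  intens <- meta$intensity_min + intens * (meta$intensity_max - meta$intensity_min)
  video_sample(intens, meta$deg_per_px, meta$frame_rate,
               environment = meta$environment)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
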