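#' Camera model for frame ingest
#'
#' Describes how stored frames map to view directions and linear light.
#' Three projections are supported: `"identity"` for frames that are
#' already rectified (synthetic input; maps angular offsets straight to
#' pixels at `deg_per_px`), `"pinhole"` (perspective), and
#' `"equidistant-fisheye"` (`r = f * theta`). The linearization is a
#' monotone lookup from stored code values to linear intensity; codes
#' between table entries are linearly interpolated so that prefiltered
#' (non-integer) codes remain valid.
#'
#' @param projection `"identity"`, `"pinhole"` or `"equidistant-fisheye"`.
#' @param focal_px Focal length in pixels (pinhole, fisheye).
#' @param center_px Principal point `c(x, y)` in pixels; defaults to the
#'   frame centre at ingest time.
#' @param deg_per_px Source angular sampling (identity projection only).
#' @param linearization Either `NULL` (identity mapping), a numeric vector
#'   of linear values for codes `0 .. max_code`, or a function of code.
#' @param max_code The camera's maximum stored intensity code (e.g. 255).
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(projection = c("identity", "pinhole",
                                        "equidistant-fisheye"),
                         focal_px = NULL, center_px = NULL,
                         deg_per_px = NULL,
                         linearization = NULL, max_code = 255) {
  projection <- match.arg(projection)
  if (projection != "identity" && is.null(focal_px)) {
    stop("focal_px is required for ", projection, " projection", call. = FALSE)
  }
  if (projection == "identity" && is.null(deg_per_px)) {
    stop("deg_per_px is required for the identity projection", call. = FALSE)
  }
  if (is.numeric(linearization)) {
    if (is.unsorted(linearization)) {
      stop("linearization lookup must be monotone non-decreasing",
           call. = FALSE)
    }
    if (length(linearization) != max_code + 1) {
      stop("linearization lookup must have max_code + 1 entries",
           call. = FALSE)
    }
  }
  structure(
    list(projection = projection, focal_px = focal_px,
         center_px = center_px, deg_per_px = deg_per_px,
         linearization = linearization, max_code = max_code),
    class = "camera_model"
  )
}

#' Load a frame sequence from disk
#'
#' Reads a directory of equal-sized PNG frames (sorted by filename) into a
#' stored-code stack. For RGB frames only the green channel is retained;
#' the analyses in this package are green-channel only. MP4 input is part
#' of the interface but no video codec is available to this package, so an
#' MP4 path raises an unsupported-format error; extract frames to PNG
#' first.
#'
#' @param path Directory of PNG frames (or an `.mp4` file, unsupported).
#' @param camera A [camera_model()]; codes are checked against
#'   `camera$max_code`.
#' @param frame_rate Frames per second of the recording. Default 100.
#' @return A `frame_stack`: list with `codes` (3-D array, y-by-x-by-t,
#'   stored code values), `frame_rate`, and `linear = NULL` until
#'   [linearize()] is applied.
#' @export
load_frames <- function(path, camera, frame_rate = 100) {
  stopifnot(inherits(camera, "camera_model"))
  if (grepl("\\.mp4$", path, ignore.case = TRUE)) {
    stop("MP4 input is not supported (no codec available); ",
         "extract frames to a PNG directory first", call. = FALSE)
  }
  if (!dir.exists(path)) stop("not a directory: ", path, call. = FALSE)
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("no PNG frames in ", path, call. = FALSE)
  frames <- lapply(files, png::readPNG)
  dims <- lapply(frames, function(f) dim(f)[1:2])
  if (length(unique(dims)) != 1) {
    stop("frames have unequal sizes", call. = FALSE)
  }
  d <- dims[[1]]
  codes <- array(0, dim = c(d[1], d[2], length(frames)))
  for (t in seq_along(frames)) {
    f <- frames[[t]]
    if (length(dim(f)) == 3) f <- f[, , 2]   # green channel
    codes[, , t] <- f * camera$max_code      # png stores [0,1]
  }
  structure(list(codes = codes, linear = NULL, frame_rate = frame_rate),
            class = "frame_stack")
}

#' Linearize stored codes to light intensity
#'
#' Replaces each stored code by its calibrated linear intensity via the
#' camera's monotone lookup. Code monotonicity is preserved, which is what
#' makes the 256-level entropy measure invariant to the camera
#' nonlinearity. Codes between integer table entries (after prefiltering)
#' are linearly interpolated; codes outside the lookup domain are an
#' error.
#'
#' @param stack A `frame_stack` from [load_frames()].
#' @param camera A [camera_model()].
#' @return The stack with `linear` filled in (codes retained).
#' @export
linearize <- function(stack, camera) {
  stopifnot(inherits(stack, "frame_stack"), inherits(camera, "camera_model"))
  codes <- stack$codes
  if (any(codes < 0 | codes > camera$max_code)) {
    stop("stored codes outside the lookup domain [0, max_code]",
         call. = FALSE)
  }
  lut <- camera$linearization
  stack$linear <- if (is.null(lut)) {
    codes
  } else if (is.function(lut)) {
    array(lut(codes), dim = dim(codes))
  } else {
    array(stats::approx(x = 0:camera$max_code, y = lut, xout = codes,
                        rule = 2)$y,
          dim = dim(codes))
  }
  stack
}

# separable Gaussian smoothing of one matrix; kernel truncated at 4 sigma,
# renormalized to unit sum, replicate-padded borders
gaussian_kernel_1d <- function(sigma, truncate = 4) {
  half <- max(1L, ceiling(truncate * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k / sum(k)
}

convolve_sep <- function(mat, kernel) {
  half <- (length(kernel) - 1L) / 2L
  pad_idx <- function(n) pmin(pmax(seq(1 - half, n + half), 1L), n)
  m <- mat[pad_idx(nrow(mat)), , drop = FALSE]
  m <- apply(m, 2, function(col) stats::filter(col, kernel, sides = 2))
  m <- m[(half + 1):(half + nrow(mat)), , drop = FALSE]
  m <- m[, pad_idx(ncol(mat)), drop = FALSE]
  m <- t(apply(m, 1, function(row) stats::filter(row, kernel, sides = 2)))
  m[, (half + 1):(half + ncol(mat)), drop = FALSE]
}

#' Gaussian prefilter of raw frames
#'
#' Smooths each raw (pre-rectification) frame with an isotropic Gaussian
#' of standard deviation `sigma_px` source pixels, used to suppress video
#' compression blocking artifacts. `sigma_px = 0` is the identity.
#'
#' @param stack A `frame_stack`.
#' @param sigma_px Kernel standard deviation in pixels (>= 0). Default 2.
#' @return The stack with smoothed codes.
#' @export
prefilter <- function(stack, sigma_px = 2) {
  stopifnot(inherits(stack, "frame_stack"))
  if (sigma_px < 0) stop("sigma_px must be >= 0", call. = FALSE)
  if (sigma_px == 0) return(stack)
  k <- gaussian_kernel_1d(sigma_px)
  for (t in seq_len(dim(stack$codes)[3])) {
    stack$codes[, , t] <- convolve_sep(stack$codes[, , t], k)
  }
  if (!is.null(stack$linear)) {
    warning("prefilter applied after linearization; pipeline order is ",
            "prefilter then linearize", call. = FALSE)
  }
  stack
}

#' Sampling window for region extraction
#'
#' A square region of the visual field, `extent` degrees on a side,
#' centred at (`azimuth_center`, `elevation_center`), rectified onto an
#' `output_resolution`-pixel grid (default 225 px over 75 degrees, i.e.
#' 1/3 degree per pixel) over the final `duration` seconds of a recording.
#'
#' @param azimuth_center,elevation_center Window centre, degrees.
#' @param extent Side length, degrees.
#' @param duration Temporal span, seconds (inclusive of both end frames).
#' @param output_resolution Output pixels per side.
#' @return An object of class `sample_window`.
#' @export
sample_window <- function(azimuth_center = 38, elevation_center = 0,
                          extent = 75, duration = 10,
                          output_resolution = 225L) {
  if (extent <= 0 || output_resolution < 2) {
    stop("extent must be > 0 and output_resolution >= 2", call. = FALSE)
  }
  structure(
    list(azimuth_center = azimuth_center,
         elevation_center = elevation_center,
         extent = extent, duration = duration,
         output_resolution = as.integer(output_resolution)),
    class = "sample_window"
  )
}

deg2rad <- function(x) x * pi / 180

# unit view ray for azimuth/elevation in radians:
# x right, y up, z forward
ray_from_angles <- function(az, el) {
  cbind(cos(el) * sin(az), sin(el), cos(el) * cos(az))
}

# project unit rays (n x 3) to source pixel coordinates (x, y), 1-based
project_rays <- function(rays, camera, frame_dim) {
  cx <- if (is.null(camera$center_px)) (frame_dim[2] + 1) / 2 else camera$center_px[1]
  cy <- if (is.null(camera$center_px)) (frame_dim[1] + 1) / 2 else camera$center_px[2]
  X <- rays[, 1]; Y <- rays[, 2]; Z <- rays[, 3]
  if (camera$projection == "pinhole") {
    if (any(Z <= 0)) stop("window exceeds the pinhole field of view",
                          call. = FALSE)
    cbind(cx + camera$focal_px * X / Z, cy - camera$focal_px * Y / Z)
  } else if (camera$projection == "equidistant-fisheye") {
    theta <- acos(pmin(pmax(Z, -1), 1))
    phi <- atan2(-Y, X)
    r <- camera$focal_px * theta
    cbind(cx + r * cos(phi), cy + r * sin(phi))
  } else {
    stop("identity cameras address pixels by angle, not rays", call. = FALSE)
  }
}

interp_bilinear <- function(mat, px, py) {
  nx <- ncol(mat); ny <- nrow(mat)
  x0 <- floor(px); y0 <- floor(py)
  x0 <- pmin(pmax(x0, 1L), nx - 1L)
  y0 <- pmin(pmax(y0, 1L), ny - 1L)
  fx <- pmin(pmax(px - x0, 0), 1)
  fy <- pmin(pmax(py - y0, 0), 1)
  i00 <- cbind(y0, x0); i01 <- cbind(y0, x0 + 1L)
  i10 <- cbind(y0 + 1L, x0); i11 <- cbind(y0 + 1L, x0 + 1L)
  mat[i00] * (1 - fx) * (1 - fy) + mat[i01] * fx * (1 - fy) +
    mat[i10] * (1 - fx) * fy + mat[i11] * fx * fy
}

# source pixel coordinates for the rectified output grid of `window`
rectify_grid <- function(window, camera, frame_dim) {
  n <- window$output_resolution
  half <- window$extent / 2
  ang <- deg2rad(seq(-half, half, length.out = n))
  if (camera$projection == "identity") {
    cx <- if (is.null(camera$center_px)) (frame_dim[2] + 1) / 2 else camera$center_px[1]
    cy <- if (is.null(camera$center_px)) (frame_dim[1] + 1) / 2 else camera$center_px[2]
    px_col <- cx + (window$azimuth_center +
                      seq(-half, half, length.out = n)) / camera$deg_per_px
    py_row <- cy - (window$elevation_center +
                      seq(half, -half, length.out = n)) / camera$deg_per_px
    list(px = matrix(rep(px_col, each = n), n, n),
         py = matrix(rep(py_row, n), n, n))
  } else {
    az0 <- deg2rad(window$azimuth_center)
    el0 <- deg2rad(window$elevation_center)
    centre <- c(cos(el0) * sin(az0), sin(el0), cos(el0) * cos(az0))
    e_right <- c(cos(az0), 0, -sin(az0))
    e_up <- c(-sin(el0) * sin(az0), cos(el0), -sin(el0) * cos(az0))
    u <- tan(ang)                     # gnomonic plane coordinates
    v <- tan(ang)
    uu <- rep(u, each = n)            # columns: azimuth
    vv <- rep(rev(v), n)              # rows: top of field first
    pts <- cbind(
      centre[1] + uu * e_right[1] + vv * e_up[1],
      centre[2] + uu * e_right[2] + vv * e_up[2],
      centre[3] + uu * e_right[3] + vv * e_up[3]
    )
    rays <- pts / sqrt(rowSums(pts^2))
    pc <- project_rays(rays, camera, frame_dim)
    list(px = matrix(pc[, 1], n, n), py = matrix(pc[, 2], n, n))
  }
}

#' Extract a rectified sample from a linearized frame stack
#'
#' Performs a gnomonic (perspective) projection of the window onto a plane
#' orthogonal to the view ray at the window centre, sampled on an
#' `output_resolution` grid spanning `extent` degrees with bilinear
#' interpolation from the source frames. The temporal span is the final
#' `duration` seconds of the stack, inclusive of both end frames (10 s at
#' 100 fps gives 1001 frames). Stored codes are carried along by
#' nearest-neighbour sampling so clipping can still be assessed against the
#' camera's code range.
#'
#' @param stack A linearized `frame_stack` (see [linearize()]).
#' @param window A [sample_window()].
#' @param camera The [camera_model()] the frames were recorded with.
#' @param environment Environment label for the sample.
#' @return A [video_sample()] with `codes` attached.
#' @export
extract_sample <- function(stack, window, camera,
                           environment = "synthetic") {
  stopifnot(inherits(stack, "frame_stack"), inherits(window, "sample_window"),
            inherits(camera, "camera_model"))
  if (is.null(stack$linear)) {
    stop("stack must be linearized before extraction; call linearize()",
         call. = FALSE)
  }
  d <- dim(stack$linear)
  n_req <- round(window$duration * stack$frame_rate) + 1L
  if (n_req > d[3]) {
    stop("recording too short for the requested duration", call. = FALSE)
  }
  t_idx <- seq(d[3] - n_req + 1L, d[3])

  grid <- rectify_grid(window, camera, d[1:2])
  if (any(grid$px < 0.5 | grid$px > d[2] + 0.5 |
          grid$py < 0.5 | grid$py > d[1] + 0.5)) {
    stop("window exceeds the source field of view", call. = FALSE)
  }
  n <- window$output_resolution
  intens <- array(0, dim = c(n, n, length(t_idx)))
  codes <- array(0, dim = c(n, n, length(t_idx)))
  nn_row <- pmin(pmax(round(grid$py), 1L), d[1])
  nn_col <- pmin(pmax(round(grid$px), 1L), d[2])
  nn_idx <- cbind(as.vector(nn_row), as.vector(nn_col))
  for (k in seq_along(t_idx)) {
    src <- stack$linear[, , t_idx[k]]
    intens[, , k] <- matrix(
      interp_bilinear(src, as.vector(grid$px), as.vector(grid$py)), n, n)
    codes[, , k] <- matrix(stack$codes[, , t_idx[k]][nn_idx], n, n)
  }
  out <- video_sample(intens, window$extent / n, stack$frame_rate,
                      environment = environment)
  out$codes <- codes
  out
}

#' Clipping assessment of a sample
#'
#' Flags pixel-frames whose stored codes fall in the bottom or top
#' `low_q`/`high_q` of the camera's code range (default 2% each). A sample
#' whose flagged fraction reaches `exclude_threshold` (default 10%,
#' boundary inclusive) is marked for exclusion; for surviving samples the
#' flagged pixels should be masked out of contrast analyses via
#' [mask_clipped()] while remaining available to spectral analysis.
#'
#' @param sample A [video_sample()]; uses its `codes` if present, else its
#'   intensities against their own maximum.
#' @param camera Optional [camera_model()] supplying `max_code`.
#' @param low_q,high_q Clip band widths as fractions of `max_code`.
#' @param exclude_threshold Exclusion threshold on the flagged fraction.
#' @return A `clipping_report`: list with `low_fraction`, `high_fraction`,
#'   `excluded_sample`, `clipped_mask`.
#' @export
clipping_check <- function(sample, camera = NULL,
                           low_q = 0.02, high_q = 0.02,
                           exclude_threshold = 0.10) {
  stopifnot(inherits(sample, "video_sample"))
  codes <- if (!is.null(sample$codes)) sample$codes else sample$intensities
  max_code <- if (!is.null(camera)) camera$max_code else max(codes)
  low <- codes <= low_q * max_code
  high <- codes >= (1 - high_q) * max_code
  low_fraction <- mean(low)
  high_fraction <- mean(high)
  structure(
    list(low_fraction = low_fraction, high_fraction = high_fraction,
         excluded_sample = (low_fraction + high_fraction) >= exclude_threshold,
         clipped_mask = low | high),
    class = "clipping_report"
  )
}

#' Mask clipped pixels out of contrast analyses
#'
#' @param sample A [video_sample()].
#' @param report A `clipping_report` from [clipping_check()].
#' @return The sample with clipped pixel-frames removed from `valid_mask`.
#' @export
mask_clipped <- function(sample, report) {
  stopifnot(inherits(sample, "video_sample"),
            inherits(report, "clipping_report"))
  sample$valid_mask <- sample$valid_mask & !report$clipped_mask
  sample
}
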