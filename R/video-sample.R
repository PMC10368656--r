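#' Video sample container
#'
#' A `video_sample` holds a rectified block of linear light intensities
#' `I(x, y, t)` together with its angular and temporal calibration and an
#' optional validity mask. It is the common currency of the package: the
#' synthetic generators produce one, the ingest pipeline extracts one from
#' frame stacks, and every analysis stage consumes one. Rows follow the
#' visual-field convention: row 1 is the top of the visual field.
#'
#' @param intensities Numeric 3-D array `(y, x, t)` of linear intensities.
#'   All unmasked values must be finite and non-negative.
#' @param deg_per_px Angular sampling, degrees per pixel (> 0).
#' @param frame_rate Temporal sampling, frames per second (> 0).
#' @param environment One of `"aquatic"`, `"terrestrial"`, `"synthetic"`.
#' @param valid_mask Logical array of the same shape; `FALSE` marks
#'   pixel-frames excluded from contrast analyses (e.g. clipped pixels).
#'   Default: all valid.
#' @param codes Optional integer array of stored (pre-linearization) code
#'   values, kept so entropy can be computed on the camera's discrete
#'   quantization classes.
#'
#' @return An object of class `video_sample`.
#' @export
video_sample <- function(intensities, deg_per_px, frame_rate,
                         environment = "synthetic",
                         valid_mask = NULL, codes = NULL) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L) {
    stop("`intensities` must be a 3-D array (y, x, t)", call. = FALSE)
  }
  if (!is.numeric(deg_per_px) || length(deg_per_px) != 1L || deg_per_px <= 0) {
    stop("`deg_per_px` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0) {
    stop("`frame_rate` must be a single positive number", call. = FALSE)
  }
  environment <- match.arg(environment, c("aquatic", "terrestrial", "synthetic"))
  if (is.null(valid_mask)) {
    valid_mask <- array(TRUE, dim = dim(intensities))
  }
  if (!identical(dim(valid_mask), dim(intensities))) {
    stop("`valid_mask` must match the shape of `intensities`", call. = FALSE)
  }
  vals <- intensities[valid_mask]
  if (any(!is.finite(vals))) {
    stop("unmasked intensities must be finite", call. = FALSE)
  }
  if (any(vals < 0)) {
    stop("unmasked intensities must be non-negative", call. = FALSE)
  }
  structure(
    list(
      intensities = intensities,
      valid_mask = valid_mask,
      deg_per_px = deg_per_px,
      frame_rate = frame_rate,
      environment = environment,
      codes = codes
    ),
    class = "video_sample"
  )
}

#' @export
print.video_sample <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<video_sample> %d x %d px, %d frames | %.4g deg/px, %.4g fps | %s\n",
    d[1], d[2], d[3], x$deg_per_px, x$frame_rate, x$environment
  ))
  n_bad <- sum(!x$valid_mask)
  if (n_bad > 0) {
    cat(sprintf("  masked pixel-frames: %d (%.2f%%)\n",
                n_bad, 100 * n_bad / length(x$valid_mask)))
  }
  invisible(x)
}

#' @export
dim.video_sample <- function(x) dim(x$intensities)

#' Per-frame mean intensity trace
#'
#' Mean of the unmasked linear intensities in each frame, as plotted under
#' each example frame in habitat-survey figures. A frame with no valid
#' pixels yields `NA`.
#'
#' @param sample A [video_sample()].
#' @return A tibble with columns `frame`, `time_s`, `mean_intensity`.
#' @export
mean_intensity_trace <- function(sample) {
  stopifnot(inherits(sample, "video_sample"))
  d <- dim(sample$intensities)
  means <- vapply(seq_len(d[3]), function(t) {
    v <- sample$intensities[, , t][sample$valid_mask[, , t]]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  tibble::tibble(
    frame = seq_len(d[3]),
    time_s = (seq_len(d[3]) - 1) / sample$frame_rate,
    mean_intensity = means
  )
}
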