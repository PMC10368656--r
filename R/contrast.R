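#' Contrast fields
#'
#' A `contrast_field` holds per-pixel contrast values of one sample, either
#' global contrast, `C = (I - Ibar) / Ibar` with `Ibar` the spatiotemporal
#' mean intensity over all unmasked pixels of the sample, or local
#' contrast, a zero-sum difference-of-Gaussians filter response divided by
#' the local (surround-Gaussian) mean luminance. Masked entries are
#' excluded from every summary.
#'
#' @name contrast-fields
NULL

new_contrast_field <- function(values, kind, valid_mask, deg_per_px,
                               environment, codes = NULL) {
  structure(
    list(values = values, kind = kind, valid_mask = valid_mask,
         deg_per_px = deg_per_px, environment = environment, codes = codes),
    class = "contrast_field"
  )
}

#' @export
print.contrast_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<contrast_field:%s> %d x %d px, %d frames | %s\n",
              x$kind, d[1], d[2], d[3], x$environment))
  invisible(x)
}

#' Global contrast of a sample
#'
#' `C(x, y, t) = (I(x, y, t) - Ibar) / Ibar`, where `Ibar` is the average
#' intensity across all unmasked pixels of the whole sample (the full
#' window over its full duration). The normalization discounts overall
#' light level, so the mean contrast of an unmasked sample is zero by
#' definition and values are bounded below by -1 for non-negative
#' intensities.
#'
#' @param sample A [video_sample()].
#' @return A `contrast_field` of kind `"global"`.
#' @export
global_contrast <- function(sample) {
  stopifnot(inherits(sample, "video_sample"))
  vals <- sample$intensities[sample$valid_mask]
  if (length(vals) == 0) stop("sample is fully masked", call. = FALSE)
  ibar <- mean(vals)
  if (!is.finite(ibar) || ibar <= 0) {
    stop("mean intensity must be positive to define global contrast",
         call. = FALSE)
  }
  new_contrast_field((sample$intensities - ibar) / ibar, "global",
                     sample$valid_mask, sample$deg_per_px,
                     sample$environment, codes = sample$codes)
}

#' Difference-of-Gaussians specification for local contrast
#'
#' Centre and surround standard deviations are given in degrees (defaults
#' 1 and 2 degrees) and converted to pixels through `deg_per_px`; at the
#' default 1/3 degree-per-pixel sampling these are 3 and 6 pixels.
#'
#' @param sigma_center_deg,sigma_surround_deg Gaussian SDs in degrees,
#'   `0 < sigma_center_deg < sigma_surround_deg`.
#' @param deg_per_px Angular sampling of the target sample.
#' @return An object of class `dog_spec` with pixel-domain sigmas.
#' @export
dog_spec <- function(sigma_center_deg = 1, sigma_surround_deg = 2,
                     deg_per_px = 1 / 3) {
  if (!(sigma_surround_deg > sigma_center_deg && sigma_center_deg > 0)) {
    stop("need sigma_surround_deg > sigma_center_deg > 0", call. = FALSE)
  }
  structure(
    list(sigma_center_deg = sigma_center_deg,
         sigma_surround_deg = sigma_surround_deg,
         deg_per_px = deg_per_px,
         sigma_center_px = sigma_center_deg / deg_per_px,
         sigma_surround_px = sigma_surround_deg / deg_per_px),
    class = "dog_spec"
  )
}

#' Locally-normalized difference-of-Gaussians contrast
#'
#' Convolves each frame with a zero-sum isotropic difference of unit-sum
#' Gaussians and normalizes by the local mean luminance (the response of
#' the unit-sum surround Gaussian):
#' `C_L = (I * (g_center - g_surround)) / (I * g_surround)`.
#' Kernels are truncated at 4 surround sigmas; a border of the same width
#' is removed from the result so edge artifacts never enter summary
#' statistics.
#'
#' @param sample A [video_sample()].
#' @param dog A [dog_spec()]; defaults to 1/2 degree centre/surround at the
#'   sample's own `deg_per_px`.
#' @return A `contrast_field` of kind `"local"` with the border cropped.
#' @export
local_contrast <- function(sample, dog = NULL) {
  stopifnot(inherits(sample, "video_sample"))
  if (is.null(dog)) dog <- dog_spec(deg_per_px = sample$deg_per_px)
  kc <- gaussian_kernel_1d(dog$sigma_center_px)
  ks <- gaussian_kernel_1d(dog$sigma_surround_px)
  border <- ceiling(4 * dog$sigma_surround_px)
  d <- dim(sample$intensities)
  if (d[1] <= 2 * border + 1 || d[2] <= 2 * border + 1) {
    stop("frame smaller than the DoG kernel support", call. = FALSE)
  }
  keep_r <- (border + 1):(d[1] - border)
  keep_c <- (border + 1):(d[2] - border)
  out <- array(0, dim = c(length(keep_r), length(keep_c), d[3]))
  for (t in seq_len(d[3])) {
    frame <- sample$intensities[, , t]
    centre <- convolve_sep(frame, kc)
    surround <- convolve_sep(frame, ks)
    num <- (centre - surround)[keep_r, keep_c]
    den <- surround[keep_r, keep_c]
    if (any(den <= 0)) {
      stop("non-positive local mean luminance in the retained region",
           call. = FALSE)
    }
    out[, , t] <- num / den
  }
  new_contrast_field(out, "local",
                     sample$valid_mask[keep_r, keep_c, , drop = FALSE],
                     sample$deg_per_px, sample$environment)
}

# population (biased) central-moment summaries of a value vector
moment_summary <- function(v) {
  n <- length(v)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  m3 <- mean((v - m)^3)
  m4 <- mean((v - m)^4)
  tibble::tibble(
    mean_contrast = m,
    variance = m2,
    skewness = if (m2 > 0) m3 / m2^1.5 else NA_real_,
    kurtosis = if (m2 > 0) m4 / m2^2 else NA_real_,
    prop_negative = mean(v < 0),
    n = n
  )
}

#' Distributional moments of a contrast field
#'
#' Variance, skewness (`m3 / m2^1.5`), non-excess kurtosis (`m4 / m2^2`,
#' Gaussian reference 3), and the proportion of strictly negative values,
#' pooled over all unmasked pixel-frames of the sample. Population
#' (biased) moment estimators are used. Zero-variance input yields missing
#' skewness and kurtosis.
#'
#' @param field A `contrast_field`.
#' @return A one-row tibble with `mean_contrast`, `variance`, `skewness`,
#'   `kurtosis`, `prop_negative`, `n`.
#' @export
contrast_moments <- function(field) {
  stopifnot(inherits(field, "contrast_field"))
  v <- field$values[field$valid_mask]
  if (length(v) < 2) stop("need at least 2 unmasked values", call. = FALSE)
  moment_summary(v)
}

#' Probability density of contrast over a fixed range
#'
#' Linearly spaced bins on `[lo, hi]` (default -1 to 4); out-of-range
#' values accumulate into the end bins; densities are normalized so that
#' `sum(density * bin_width) = 1`.
#'
#' @param field A `contrast_field`.
#' @param lo,hi Range of the binning grid.
#' @param n_bins Number of bins (default 100).
#' @return A tibble with `bin_lo`, `bin_hi`, `bin_mid`, `density`.
#' @export
contrast_density <- function(field, lo = -1, hi = 4, n_bins = 100) {
  stopifnot(inherits(field, "contrast_field"), n_bins >= 2)
  v <- field$values[field$valid_mask]
  if (length(v) == 0) stop("empty contrast field", call. = FALSE)
  edges <- seq(lo, hi, length.out = n_bins + 1)
  width <- diff(edges)[1]
  idx <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  tibble::tibble(
    bin_lo = edges[-(n_bins + 1)],
    bin_hi = edges[-1],
    bin_mid = (edges[-1] + edges[-(n_bins + 1)]) / 2,
    density = counts / sum(counts) / width
  )
}

shannon_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Shannon entropy of a sample's discrete level distribution
#'
#' Entropy `H = -sum p(C_i) log2 p(C_i)` over `n_levels` discrete levels
#' (default 256, i.e. 8 bits). Levels are the stored-code quantization
#' classes of the sample's pixels when codes are available; contrast is a
#' monotone relabeling of the codes within a sample, so this is
#' well-defined and invariant to any strictly monotone intensity
#' transform. Without codes, values with at most `n_levels` distinct
#' levels are treated as discrete symbols; otherwise they are quantized
#' into `n_levels` equal-width bins over their observed range.
#'
#' @param field A `contrast_field` (or [video_sample()]).
#' @param n_levels Number of discrete levels. Default 256.
#' @return Entropy in bits, in `[0, log2(n_levels)]`.
#' @export
contrast_entropy <- function(field, n_levels = 256) {
  v_all <- if (inherits(field, "video_sample")) {
    list(values = field$intensities, mask = field$valid_mask,
         codes = field$codes)
  } else {
    list(values = field$values, mask = field$valid_mask,
         codes = field$codes)
  }
  src <- if (!is.null(v_all$codes)) v_all$codes else v_all$values
  v <- src[v_all$mask]
  if (length(v) == 0) stop("no unmasked values", call. = FALSE)
  lv <- unique(v)
  p <- if (length(lv) <= n_levels) {
    tabulate(match(v, lv)) / length(v)
  } else {
    rng <- range(v)
    edges <- seq(rng[1], rng[2], length.out = n_levels + 1)
    idx <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L),
                n_levels)
    tabulate(idx, nbins = n_levels) / length(v)
  }
  shannon_bits(p)
}

# row indices for the two hemifields; middle row of odd grids excluded
hemifield_rows <- function(n_rows) {
  half <- n_rows %/% 2
  list(upper = seq_len(half),
       lower = seq(n_rows - half + 1, n_rows))
}

#' Hemifield contrast summaries
#'
#' Splits the field at the elevation-zero midline (row 1 is the top of the
#' visual field) and computes the full moment summary separately for the
#' upper and lower hemifields. For odd row counts the middle row belongs
#' to neither hemifield. The hemifield mean contrast is reported relative
#' to the whole-field normalization, so a top-bright illumination gradient
#' shows up as positive upper-field and negative lower-field mean
#' contrast.
#'
#' @param field A `contrast_field`.
#' @return A tibble with one row per hemifield (`"upper"`, `"lower"`) and
#'   the [contrast_moments()] columns.
#' @export
hemifield_summaries <- function(field) {
  stopifnot(inherits(field, "contrast_field"))
  rows <- hemifield_rows(dim(field$values)[1])
  purrr::map_dfr(c("upper", "lower"), function(h) {
    vv <- field$values[rows[[h]], , , drop = FALSE]
    mm <- field$valid_mask[rows[[h]], , , drop = FALSE]
    dplyr::bind_cols(tibble::tibble(hemifield = h), moment_summary(vv[mm]))
  })
}

#' Per-pixel median contrast map
#'
#' Median contrast at each pixel over all frames of all supplied fields
#' (which must share a grid), ignoring masked entries; a pixel masked
#' everywhere yields `NA`. This is the heatmap view of where bright and
#' dark contrasts live in the visual field.
#'
#' @param fields A list of `contrast_field`s with a common grid.
#' @return A numeric matrix (rows = top of visual field first).
#' @export
median_contrast_map <- function(fields) {
  if (inherits(fields, "contrast_field")) fields <- list(fields)
  stopifnot(length(fields) >= 1)
  d <- dim(fields[[1]]$values)[1:2]
  for (f in fields) {
    if (!identical(dim(f$values)[1:2], d)) {
      stop("all fields must share the same grid", call. = FALSE)
    }
  }
  vals <- do.call(abind3, lapply(fields, function(f) {
    v <- f$values
    v[!f$valid_mask] <- NA
    v
  }))
  apply(vals, c(1, 2), stats::median, na.rm = TRUE)
}

# bind 3-D arrays along the third dimension
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])[1:2]
  nt <- sum(vapply(arrs, function(a) dim(a)[3], numeric(1)))
  out <- array(NA_real_, dim = c(d[1], d[2], nt))
  at <- 0L
  for (a in arrs) {
    k <- dim(a)[3]
    out[, , at + seq_len(k)] <- a
    at <- at + k
  }
  out
}
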