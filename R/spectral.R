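#' Spatiotemporal power spectra
#'
#' The spectral pipeline mirrors the standard natural-scene-statistics
#' recipe: subtract the mean, apply a separable 3-D Hann window, take the
#' 3-D FFT, and square the amplitudes. Power is then grouped into
#' log-spaced bins: spatial frequency as rings of radial frequency
#' `r = sqrt(f_x^2 + f_y^2)` (all orientations pooled) and temporal
#' frequency folded to `|f_t|`, 19 bins per axis spanning 0.05-0.75
#' cycles/degree and 0.5-50 cycles/second by default (361 joint cells).
#'
#' @name spectral-analysis
NULL

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))
}

#' Windowed 3-D power spectrum of a sample
#'
#' Subtracts the spatiotemporal mean, applies a separable 3-D Hann window
#' (product of per-axis Hann windows), performs the 3-D FFT and returns
#' squared amplitudes. Mean subtraction precedes windowing so the window
#' cannot reintroduce a DC pedestal. The Parseval identity
#' `sum(power) / N = sum(windowed signal^2)` holds exactly up to floating
#' error. Clipped pixels are retained at their linear values here;
#' exclusion applies to contrast analyses only.
#'
#' @param sample A [video_sample()] with at least 8 samples per axis.
#' @return A `spectrum_grid`: list with `power` (3-D array in FFT layout),
#'   frequency axes `fy`, `fx` (cycles/degree), `ft` (cycles/second), and
#'   the window energy.
#' @export
power_spectrum_3d <- function(sample) {
  stopifnot(inherits(sample, "video_sample"))
  d <- dim(sample$intensities)
  if (any(d < 8)) stop("sample must be at least 8 samples per axis",
                       call. = FALSE)
  x <- sample$intensities - mean(sample$intensities)
  wy <- hann_window(d[1]); wx <- hann_window(d[2]); wt <- hann_window(d[3])
  w <- outer(outer(wy, wx), wt)
  dim(w) <- d
  xw <- x * w
  pow <- Mod(stats::fft(xw))^2
  structure(
    list(
      power = pow,
      fy = fft_freqs(d[1], sample$deg_per_px),
      fx = fft_freqs(d[2], sample$deg_per_px),
      ft = fft_freqs(d[3], 1 / sample$frame_rate),
      window_energy = sum(w^2),
      signal_energy = sum(xw^2)
    ),
    class = "spectrum_grid"
  )
}

log_edges <- function(lo, hi, n_bins) {
  exp(seq(log(lo), log(hi), length.out = n_bins + 1))
}

#' Log-spaced spatiotemporal binning of a raw spectrum
#'
#' Assigns every Fourier coefficient to a (radial-spatial, |temporal|)
#' frequency cell using `n_bins` bins per axis delimited by
#' logarithmically spaced edges (assignment to `[edge_i, edge_{i+1})`),
#' and records the mean power per cell. The DC coefficient and
#' coefficients outside both ranges are excluded. Bin centres are the
#' geometric means of their edges. Marginal mean-power curves are computed
#' from the raw grid (not from the joint table): mean power per spatial
#' ring over all temporal frequencies, and per temporal bin over all
#' spatial frequencies.
#'
#' @param grid A `spectrum_grid` from [power_spectrum_3d()].
#' @param f_s_range Spatial bin range, cycles/degree. Default
#'   `c(0.05, 0.75)`.
#' @param f_t_range Temporal bin range, cycles/second. Default
#'   `c(0.5, 50)`.
#' @param n_bins Bins per axis. Default 19.
#' @return A `binned_spectrum`: list with the joint mean-power matrix
#'   (`n_bins` spatial rows x `n_bins` temporal columns), bin edges and
#'   centres, and `marginals`, a tibble with columns `domain`
#'   (`"spatial"`/`"temporal"`), `freq`, `power`.
#' @export
bin_spectrum <- function(grid, f_s_range = c(0.05, 0.75),
                         f_t_range = c(0.5, 50), n_bins = 19) {
  stopifnot(inherits(grid, "spectrum_grid"))
  s_edges <- log_edges(f_s_range[1], f_s_range[2], n_bins)
  t_edges <- log_edges(f_t_range[1], f_t_range[2], n_bins)
  s_centers <- sqrt(s_edges[-1] * s_edges[-(n_bins + 1)])
  t_centers <- sqrt(t_edges[-1] * t_edges[-(n_bins + 1)])

  r <- sqrt(outer(grid$fy^2, grid$fx^2, `+`))       # ny x nx
  aft <- abs(grid$ft)
  d <- dim(grid$power)

  s_bin_xy <- findInterval(r, s_edges)              # 0..n_bins+?
  s_bin_xy[s_bin_xy > n_bins | r >= s_edges[n_bins + 1]] <- NA
  s_bin_xy[s_bin_xy < 1] <- NA
  t_bin_t <- findInterval(aft, t_edges)
  t_bin_t[t_bin_t > n_bins | aft >= t_edges[n_bins + 1]] <- NA
  t_bin_t[t_bin_t < 1] <- NA

  s_bin <- array(rep(s_bin_xy, d[3]), dim = d)
  t_bin <- array(rep(t_bin_t, each = d[1] * d[2]), dim = d)

  keep <- !is.na(s_bin) & !is.na(t_bin)
  cell <- (s_bin[keep] - 1L) + n_bins * (t_bin[keep] - 1L)
  sums <- tapply(grid$power[keep], cell, sum)
  counts <- table(cell)
  joint <- matrix(NA_real_, n_bins, n_bins)
  idx <- as.integer(names(sums)) + 1L
  joint[idx] <- as.numeric(sums) / as.numeric(counts)
  if (anyNA(joint)) {
    warning("some spatiotemporal cells contain no Fourier coefficients",
            call. = FALSE)
  }

  marg <- marginal_spectra(grid, f_s_range = f_s_range,
                           f_t_range = f_t_range, n_bins = n_bins)
  structure(
    list(joint = joint,
         spatial_edges = s_edges, temporal_edges = t_edges,
         spatial_centers = s_centers, temporal_centers = t_centers,
         marginals = marg),
    class = "binned_spectrum"
  )
}

#' Marginal mean-power spectra
#'
#' Mean power as a function of spatial frequency (per ring bin, over all
#' temporal frequencies) and of temporal frequency (per bin of `|f_t|`,
#' over all spatial frequencies), computed from the raw spectrum grid.
#'
#' @inheritParams bin_spectrum
#' @return A tibble with columns `domain`, `freq`, `power`.
#' @export
marginal_spectra <- function(grid, f_s_range = c(0.05, 0.75),
                             f_t_range = c(0.5, 50), n_bins = 19) {
  stopifnot(inherits(grid, "spectrum_grid"))
  s_edges <- log_edges(f_s_range[1], f_s_range[2], n_bins)
  t_edges <- log_edges(f_t_range[1], f_t_range[2], n_bins)
  s_centers <- sqrt(s_edges[-1] * s_edges[-(n_bins + 1)])
  t_centers <- sqrt(t_edges[-1] * t_edges[-(n_bins + 1)])
  d <- dim(grid$power)

  r <- sqrt(outer(grid$fy^2, grid$fx^2, `+`))
  s_bin_xy <- findInterval(r, s_edges)
  s_bin_xy[s_bin_xy < 1 | s_bin_xy > n_bins | r >= s_edges[n_bins + 1]] <- NA
  s_power <- vapply(seq_len(n_bins), function(b) {
    sel <- which(s_bin_xy == b)
    if (length(sel) == 0) return(NA_real_)
    tot <- 0
    for (t in seq_len(d[3])) tot <- tot + sum(grid$power[, , t][sel])
    tot / (length(sel) * d[3])
  }, numeric(1))

  aft <- abs(grid$ft)
  t_bin_t <- findInterval(aft, t_edges)
  t_bin_t[t_bin_t < 1 | t_bin_t > n_bins | aft >= t_edges[n_bins + 1]] <- NA
  t_power <- vapply(seq_len(n_bins), function(b) {
    sel <- which(t_bin_t == b)
    if (length(sel) == 0) return(NA_real_)
    mean(grid$power[, , sel])
  }, numeric(1))

  tibble::tibble(
    domain = rep(c("spatial", "temporal"), each = n_bins),
    freq = c(s_centers, t_centers),
    power = c(s_power, t_power)
  )
}

#' Log-log slope of a marginal power spectrum
#'
#' Ordinary least squares of `log10(power)` on `log10(freq)` over all bins
#' of a marginal curve. Bins with missing or non-positive power are
#' dropped with a warning. An exact power law is reproduced with zero
#' residual.
#'
#' @param curve A tibble with columns `freq` and `power` (one domain of
#'   [marginal_spectra()] output), or the full marginals tibble plus
#'   `domain` to select.
#' @param domain Optional domain filter (`"spatial"`/`"temporal"`).
#' @return A `slope_fit` object; see [tidy.slope_fit()].
#' @export
fit_loglog_slope <- function(curve, domain = NULL) {
  if (!is.null(domain) && "domain" %in% names(curve)) {
    curve <- curve[curve$domain == domain, ]
  }
  dom <- if (!is.null(domain)) domain
         else if ("domain" %in% names(curve)) unique(curve$domain)[1]
         else NA_character_
  ok <- is.finite(curve$power) & curve$power > 0 & is.finite(curve$freq)
  if (sum(!ok) > 0) {
    warning(sum(!ok), " bin(s) with missing or non-positive power dropped",
            call. = FALSE)
  }
  curve <- curve[ok, ]
  if (nrow(curve) < 3) stop("need at least 3 positive-power bins",
                            call. = FALSE)
  fit <- stats::lm(log10(power) ~ log10(freq), data = curve)
  sm <- suppressWarnings(summary(fit))   # exact power laws fit perfectly
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = sm$r.squared,
         residual_sd = sm$sigma,
         n_bins = nrow(curve),
         domain = dom,
         model = fit),
    class = "slope_fit"
  )
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("<slope_fit:%s> slope = %.3f (R^2 = %.3f, %d bins)\n",
              x$domain, x$slope, x$r_squared, x$n_bins))
  invisible(x)
}

#' Cellwise difference of two binned spectra with iso-speed overlay
#'
#' `log10(a) - log10(b)` per joint cell, plus each cell's iso-speed value
#' (temporal bin centre over spatial bin centre, degrees/second): cells of
#' equal ratio lie on the locus swept by patterns moving at that speed.
#' Missing cells propagate as missing.
#'
#' @param a,b `binned_spectrum` objects on identical bin grids (e.g.
#'   cellwise medians across samples from [median_spectrum()]).
#' @return A tibble with `spatial_freq`, `temporal_freq`,
#'   `diff_log10_power`, `iso_speed_deg_s`.
#' @export
spectrum_difference <- function(a, b) {
  stopifnot(inherits(a, "binned_spectrum"), inherits(b, "binned_spectrum"))
  if (!isTRUE(all.equal(a$spatial_edges, b$spatial_edges)) ||
      !isTRUE(all.equal(a$temporal_edges, b$temporal_edges))) {
    stop("binned spectra are on different grids", call. = FALSE)
  }
  n_s <- length(a$spatial_centers)
  n_t <- length(a$temporal_centers)
  tibble::tibble(
    spatial_freq = rep(a$spatial_centers, times = n_t),
    temporal_freq = rep(a$temporal_centers, each = n_s),
    diff_log10_power = as.vector(log10(a$joint) - log10(b$joint)),
    iso_speed_deg_s = rep(a$temporal_centers, each = n_s) /
      rep(a$spatial_centers, times = n_t)
  )
}

#' Cellwise median of binned spectra across samples
#'
#' The joint spectra shown for each environment are cellwise medians
#' across samples; this helper reduces a list of [bin_spectrum()] results
#' (sharing one grid) to a single `binned_spectrum` of medians.
#'
#' @param spectra A list of `binned_spectrum` objects.
#' @return A `binned_spectrum` whose joint table is the cellwise median;
#'   marginals are the bin-wise medians of the per-sample marginals.
#' @export
median_spectrum <- function(spectra) {
  stopifnot(length(spectra) >= 1)
  ref <- spectra[[1]]
  joints <- vapply(spectra, function(s) s$joint,
                   matrix(0, nrow(ref$joint), ncol(ref$joint)))
  med <- apply(joints, c(1, 2), stats::median, na.rm = TRUE)
  powers <- vapply(spectra, function(s) s$marginals$power,
                   numeric(nrow(ref$marginals)))
  marg <- ref$marginals
  marg$power <- apply(powers, 1, stats::median, na.rm = TRUE)
  out <- ref
  out$joint <- med
  out$marginals <- marg
  out
}
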