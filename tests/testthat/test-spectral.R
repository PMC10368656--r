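test_that("the windowed spectrum satisfies Parseval and kills constants", {
  s <- gaussian_sample(nx = 16, ny = 16, nt = 16, seed = 3)
  g <- power_spectrum_3d(s)
  expect_lt(abs(sum(g$power) / length(g$power) - g$signal_energy) /
              g$signal_energy, 1e-6)
  expect_true(all(g$power >= 0))
  # constant sample: zero power everywhere after mean subtraction
  gz <- power_spectrum_3d(video_sample(array(4, c(8, 8, 8)), 1, 10))
  expect_lt(max(gz$power), 1e-18)
  expect_error(power_spectrum_3d(video_sample(array(1, c(4, 8, 8)), 1, 10)),
               "8")
})

test_that("a drifting grating peaks at its spatiotemporal frequency", {
  f_s <- 6 / 32        # cycles/deg, commensurate with a 96px * 1/3 deg grid
  f_t <- 2             # Hz, commensurate with 50 frames at 100 fps
  g <- power_spectrum_3d(drifting_grating(f_s, f_t))
  peak <- which(g$power == max(g$power), arr.ind = TRUE)[1, ]
  expect_equal(abs(g$fx[peak[2]]), f_s, tolerance = 1e-9)
  expect_equal(abs(g$ft[peak[3]]), f_t, tolerance = 1e-9)
  expect_equal(abs(g$fy[peak[1]]), 0)
})

test_that("binning assigns concentrated power to the predicted cell", {
  f_s <- 6 / 32; f_t <- 2
  bs <- suppressWarnings(
    bin_spectrum(power_spectrum_3d(drifting_grating(f_s, f_t))))
  # oracle: compute the containing bin from the edge formula directly
  s_edges <- exp(seq(log(0.05), log(0.75), length.out = 20))
  t_edges <- exp(seq(log(0.5), log(50), length.out = 20))
  s_bin <- findInterval(f_s, s_edges)
  t_bin <- findInterval(f_t, t_edges)
  peak_cell <- which(bs$joint == max(bs$joint, na.rm = TRUE), arr.ind = TRUE)
  expect_equal(unname(peak_cell[1, ]), c(s_bin, t_bin))
  # edges strictly increasing and log-spaced
  expect_true(all(diff(bs$spatial_edges) > 0))
  expect_equal(diff(log(bs$temporal_edges)),
               rep(diff(log(bs$temporal_edges))[1], 19), tolerance = 1e-12)
  expect_equal(dim(bs$joint), c(19, 19))
})

test_that("ring binning is invariant to a 90-degree frame rotation", {
  s <- gaussian_sample(nx = 24, ny = 24, nt = 12, seed = 5)
  rot <- s$intensities
  for (t in seq_len(dim(rot)[3])) {
    rot[, , t] <- t(s$intensities[, , t])[, 24:1]
  }
  s_rot <- video_sample(rot, s$deg_per_px, s$frame_rate)
  rng_s <- c(0.07, 0.7); rng_t <- c(5, 45)
  b1 <- suppressWarnings(bin_spectrum(power_spectrum_3d(s),
                                      f_s_range = rng_s, f_t_range = rng_t))
  b2 <- suppressWarnings(bin_spectrum(power_spectrum_3d(s_rot),
                                      f_s_range = rng_s, f_t_range = rng_t))
  expect_equal(b1$joint, b2$joint, tolerance = 1e-9)
})

test_that("slope fits reproduce exact power laws and flat curves", {
  freq <- exp(seq(log(0.05), log(0.75), length.out = 19))
  fit2 <- fit_loglog_slope(tibble::tibble(freq = freq, power = freq^-2))
  expect_equal(glance(fit2)$slope, -2, tolerance = 1e-10)
  expect_lt(glance(fit2)$sigma, 1e-10)
  fit0 <- fit_loglog_slope(tibble::tibble(freq = freq, power = rep(3, 19)))
  expect_equal(glance(fit0)$slope, 0, tolerance = 1e-10)
  # non-positive bins dropped with a warning; too few bins error
  expect_warning(
    fit_loglog_slope(tibble::tibble(freq = freq,
                                    power = c(rep(1, 17), 0, NA))),
    "dropped")
  expect_error(
    suppressWarnings(fit_loglog_slope(
      tibble::tibble(freq = freq[1:3], power = c(1, 0, 0)))),
    "3")
  # tidy() exposes the regression terms
  td <- tidy(fit2)
  expect_equal(td$term, c("intercept", "log10(freq)"))
})

test_that("separable power-law videos recover their marginal slopes", {
  sp <- scene_spec(width_px = 96, height_px = 96, n_frames = 128,
                   spatial_slope = -2, temporal_slope = -1.5, seed = 2)
  m <- suppressWarnings(marginal_spectra(power_spectrum_3d(
    generate_powerlaw_video(sp))))
  expect_equal(glance(suppressWarnings(
    fit_loglog_slope(m, "spatial")))$slope, -2, tolerance = 0.3)
  expect_equal(glance(suppressWarnings(
    fit_loglog_slope(m, "temporal")))$slope, -1.5, tolerance = 0.3)
})

test_that("spectrum differences and iso-speed values behave as contracts", {
  s <- gaussian_sample(nx = 24, ny = 24, nt = 12, seed = 9)
  b <- suppressWarnings(bin_spectrum(power_spectrum_3d(s),
                                     f_s_range = c(0.07, 0.7),
                                     f_t_range = c(5, 45)))
  d0 <- spectrum_difference(b, b)
  expect_true(all(d0$diff_log10_power[is.finite(d0$diff_log10_power)] == 0))
  b10 <- b; b10$joint <- b$joint * 10
  d1 <- spectrum_difference(b10, b)
  expect_equal(d1$diff_log10_power[is.finite(d1$diff_log10_power)],
               rep(1, sum(is.finite(d1$diff_log10_power))), tolerance = 1e-9)
  expect_equal(d1$iso_speed_deg_s,
               d1$temporal_freq / d1$spatial_freq)
  # mismatched grids refuse to difference
  b_other <- suppressWarnings(bin_spectrum(power_spectrum_3d(s),
                                           f_s_range = c(0.08, 0.7),
                                           f_t_range = c(5, 45)))
  expect_error(spectrum_difference(b, b_other), "different grids")
})

test_that("faster dot fields shift binned power to higher iso-speed cells", {
  sc <- scene_spec(width_px = 64, height_px = 64, n_frames = 128,
                   deg_per_px = 1 / 3, frame_rate = 100)
  mk <- function(speed, seed) {
    generate_dot_video(dot_field_spec(n_dots = 12, dot_diameter_deg = 2,
                                      speed_mean = speed, seed = seed), sc)
  }
  rng_s <- c(0.06, 0.7); rng_t <- c(1.5, 45)
  weighted_iso <- function(b) {
    df <- tidy(b)
    df$iso <- df$temporal_freq / df$spatial_freq
    ok <- is.finite(df$power)
    exp(weighted.mean(log(df$iso[ok]), df$power[ok]))
  }
  b_fast <- suppressWarnings(bin_spectrum(power_spectrum_3d(mk(30, 1)),
                                          f_s_range = rng_s, f_t_range = rng_t))
  b_slow <- suppressWarnings(bin_spectrum(power_spectrum_3d(mk(5, 1)),
                                          f_s_range = rng_s, f_t_range = rng_t))
  # a pattern drifting at v concentrates power at iso-speeds up to v, so
  # the power-weighted iso-speed centre rises with the drift speed
  expect_gt(weighted_iso(b_fast), weighted_iso(b_slow))
  expect_lt(weighted_iso(b_slow), 30)
})

test_that("median spectrum reduces cellwise across samples", {
  mk <- function(seed) {
    suppressWarnings(bin_spectrum(
      power_spectrum_3d(gaussian_sample(nx = 16, ny = 16, nt = 16,
                                        seed = seed)),
      f_s_range = c(0.1, 0.7), f_t_range = c(8, 45)))
  }
  bs <- lapply(1:3, mk)
  med <- median_spectrum(bs)
  i <- which(is.finite(med$joint))[1]
  expect_equal(med$joint[i],
               median(c(bs[[1]]$joint[i], bs[[2]]$joint[i], bs[[3]]$joint[i])))
})
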