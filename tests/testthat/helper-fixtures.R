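# Shared fixtures and independent oracles, built in code at test time.

# small deterministic gaussian-intensity sample
gaussian_sample <- function(nx = 32, ny = 32, nt = 8, mean = 100, sd = 5,
                            seed = 42) {
  generate_skewed_field(scene_spec(
    width_px = nx, height_px = ny, n_frames = nt,
    intensity_model = "gaussian",
    intensity_params = list(mean = mean, sd = sd), seed = seed
  ))
}

# closed-form skewness of a lognormal with log-scale sd s
lognormal_skewness <- function(s) {
  (exp(s^2) + 2) * sqrt(exp(s^2) - 1)
}

# brute-force 2-D convolution with a separable gaussian kernel pair,
# replicate padding; independent of the package's separable filter path
brute_conv2 <- function(mat, sigma, truncate = 4) {
  half <- max(1L, ceiling(truncate * sigma))
  g <- dnorm(seq(-half, half), sd = sigma)
  k2 <- outer(g, g)
  k2 <- k2 / sum(k2)
  ny <- nrow(mat); nx <- ncol(mat)
  out <- matrix(0, ny, nx)
  for (i in seq_len(ny)) {
    for (j in seq_len(nx)) {
      acc <- 0
      for (di in -half:half) {
        for (dj in -half:half) {
          ii <- min(max(i + di, 1L), ny)
          jj <- min(max(j + dj, 1L), nx)
          acc <- acc + mat[ii, jj] * k2[di + half + 1, dj + half + 1]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# a drifting sinusoidal grating sample with frequencies commensurate with
# the grid so the spectral peak is leakage-free
drifting_grating <- function(f_s_cpd, f_t_hz, nx = 96, ny = 96, nt = 50,
                             deg_per_px = 1 / 3, frame_rate = 100) {
  x_deg <- (seq_len(nx) - 1) * deg_per_px
  t_s <- (seq_len(nt) - 1) / frame_rate
  intens <- array(0, c(ny, nx, nt))
  for (t in seq_len(nt)) {
    row <- 100 * (1 + 0.5 * sin(2 * pi * (f_s_cpd * x_deg - f_t_hz * t_s[t])))
    intens[, , t] <- matrix(rep(row, each = ny), ny, nx)
  }
  video_sample(intens, deg_per_px, frame_rate)
}
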