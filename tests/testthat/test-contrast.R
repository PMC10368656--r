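test_that("global contrast follows its defining normalization", {
  # intensities {1,2,3}: mean 2, contrasts {-0.5, 0, 0.5}
  s <- video_sample(array(rep(1:3, 64 * 3)[1:(8 * 8 * 3)], c(8, 8, 3)), 1, 10)
  f <- global_contrast(s)
  expect_setequal(unique(as.vector(f$values)), c(-0.5, 0, 0.5))
  # constant sample -> all zeros; unmasked mean is zero by definition
  cst <- global_contrast(video_sample(array(5, c(8, 8, 3)), 1, 10))
  expect_true(all(cst$values == 0))
  g <- global_contrast(gaussian_sample())
  expect_lt(abs(mean(g$values)), 1e-12)
  expect_true(all(g$values >= -1))
  # degenerate input
  expect_error(global_contrast(video_sample(array(0, c(8, 8, 8)), 1, 10)),
               "positive")
})

test_that("contrast is invariant to intensity scale", {
  s <- gaussian_sample(nx = 24, ny = 24, nt = 8)
  s2 <- video_sample(s$intensities * 7.3, s$deg_per_px, s$frame_rate)
  expect_equal(global_contrast(s2)$values, global_contrast(s)$values,
               tolerance = 1e-12)
  expect_equal(local_contrast(s2, dog_spec(deg_per_px = 1))$values,
               local_contrast(s, dog_spec(deg_per_px = 1))$values,
               tolerance = 1e-10)
})

test_that("moments use population estimators and handle edge cases", {
  v <- c(-1, 0, 0.5, 2, 3.5)
  # direct oracle on a small vector
  f <- structure(list(values = array(v, c(1, 1, 5)),
                      valid_mask = array(TRUE, c(1, 1, 5)),
                      kind = "global", deg_per_px = 1,
                      environment = "synthetic", codes = NULL),
                 class = "contrast_field")
  mom <- contrast_moments(f)
  m <- mean(v)
  expect_equal(mom$variance, mean((v - m)^2))
  expect_equal(mom$skewness, mean((v - m)^3) / mean((v - m)^2)^1.5)
  expect_equal(mom$kurtosis, mean((v - m)^4) / mean((v - m)^2)^2)
  expect_equal(mom$prop_negative, 0.2)
  # zero-variance: skewness/kurtosis reported missing
  fz <- structure(list(values = array(0, c(1, 1, 5)),
                       valid_mask = array(TRUE, c(1, 1, 5)),
                       kind = "global", deg_per_px = 1,
                       environment = "synthetic", codes = NULL),
                  class = "contrast_field")
  momz <- contrast_moments(fz)
  expect_true(is.na(momz$skewness) && is.na(momz$kurtosis))
})

test_that("a large gaussian sample is mesokurtic, symmetric, half negative", {
  mom <- contrast_moments(global_contrast(
    gaussian_sample(nx = 128, ny = 128, nt = 32, seed = 1)))
  expect_lt(abs(mom$kurtosis - 3), 0.1)
  expect_lt(abs(mom$skewness), 0.05)
  expect_lt(abs(mom$prop_negative - 0.5), 0.01)
})

test_that("contrast density integrates to one and matches direct counting", {
  f <- global_contrast(gaussian_sample(nx = 32, ny = 32, nt = 8))
  d <- contrast_density(f, n_bins = 50)
  w <- d$bin_hi - d$bin_lo
  expect_equal(sum(d$density * w), 1, tolerance = 1e-9)
  # direct histogram oracle
  v <- f$values[f$valid_mask]
  edges <- seq(-1, 4, length.out = 51)
  counts <- hist(pmin(pmax(v, -1 + 1e-12), 4 - 1e-12), breaks = edges,
                 plot = FALSE)$counts
  expect_equal(d$density, counts / sum(counts) / w[1])
  # all values equal: one occupied bin at 1/width
  fz <- global_contrast(video_sample(array(5, c(8, 8, 3)), 1, 10))
  dz <- contrast_density(fz, n_bins = 10)
  expect_equal(sum(dz$density > 0), 1)
  expect_equal(max(dz$density), 1 / 0.5)
  # uniform on [-1, 4] -> flat density 0.2
  u <- structure(list(values = array(seq(-1, 4, length.out = 4000),
                                     c(10, 10, 40)),
                      valid_mask = array(TRUE, c(10, 10, 40)),
                      kind = "global", deg_per_px = 1,
                      environment = "synthetic", codes = NULL),
                 class = "contrast_field")
  du <- contrast_density(u, n_bins = 10)
  expect_equal(du$density, rep(0.2, 10), tolerance = 0.01)
})

test_that("entropy has its closed forms and bounds", {
  mk <- function(codes) {
    arr <- array(codes, c(1, 1, length(codes)))
    video_sample(arr, 1, 1, codes = arr)
  }
  expect_equal(contrast_entropy(mk(rep(7, 100))), 0)
  expect_equal(contrast_entropy(mk(rep(0:255, 4))), 8)
  expect_equal(contrast_entropy(mk(c(1, 1, 2, 3))), 1.5)
  # bounds on an arbitrary continuous field
  f <- global_contrast(gaussian_sample(nx = 32, ny = 32, nt = 8))
  h <- contrast_entropy(f)
  expect_gte(h, 0); expect_lte(h, 8)
})

test_that("DoG local contrast matches a brute-force convolution oracle", {
  # single bright pixel on a uniform background, 32x32 frame
  frame <- matrix(100, 32, 32); frame[16, 16] <- 200
  s <- video_sample(array(frame, c(32, 32, 1)), 1, 10)
  dog <- dog_spec(sigma_center_deg = 1, sigma_surround_deg = 2, deg_per_px = 1)
  got <- local_contrast(s, dog)
  centre <- brute_conv2(frame, 1)
  surround <- brute_conv2(frame, 2)
  border <- ceiling(4 * 2)
  keep <- (border + 1):(32 - border)
  oracle <- ((centre - surround) / surround)[keep, keep]
  expect_equal(got$values[, , 1], oracle, tolerance = 1e-10)
  # constant input -> exactly zero response
  cst <- local_contrast(video_sample(array(9, c(60, 60, 2)), 1 / 3, 10))
  expect_lt(max(abs(cst$values)), 1e-10)
})

test_that("default DoG sigmas are 3 and 6 pixels at a third of a degree", {
  dog <- dog_spec(deg_per_px = 1 / 3)
  expect_equal(dog$sigma_center_px, 3)
  expect_equal(dog$sigma_surround_px, 6)
  expect_error(dog_spec(sigma_center_deg = 2, sigma_surround_deg = 1),
               "sigma")
})

test_that("hemifield summaries agree with manual splits and pool correctly", {
  f <- global_contrast(gaussian_sample(nx = 16, ny = 17, nt = 8, seed = 6))
  hs <- hemifield_summaries(f)
  # manual split: 17 rows, middle row 9 excluded
  up <- f$values[1:8, , ]; lo <- f$values[10:17, , ]
  expect_equal(hs$variance[hs$hemifield == "upper"],
               mean((up - mean(up))^2))
  expect_equal(hs$mean_contrast[hs$hemifield == "lower"], mean(lo))
  # pooling upper+lower reproduces whole-field moments minus the middle row
  pooled <- c(up, lo)
  both <- f$values[-9, , ]
  expect_equal(mean(pooled), mean(both))
  expect_equal(stats::var(pooled), stats::var(as.vector(both)))
})

test_that("median contrast map matches a per-pixel oracle", {
  f1 <- global_contrast(gaussian_sample(nx = 8, ny = 8, nt = 8, seed = 1))
  f2 <- global_contrast(gaussian_sample(nx = 8, ny = 8, nt = 8, seed = 2))
  got <- median_contrast_map(list(f1, f2))
  oracle <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    oracle[i, j] <- median(c(f1$values[i, j, ], f2$values[i, j, ]))
  }
  expect_equal(got, oracle)
  # two constant fields a, b -> per-pixel (a+b)/2
  ca <- global_contrast(video_sample(array(2, c(4, 4, 1)), 1, 1))
  ca$values[] <- 1
  cb <- ca; cb$values[] <- 3
  expect_equal(median_contrast_map(list(ca, cb)),
               matrix(2, 4, 4))
})
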