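make_stack <- function(codes, frame_rate = 100) {
  structure(list(codes = codes, linear = NULL, frame_rate = frame_rate),
            class = "frame_stack")
}

test_that("load_frames reads PNG directories and keeps the green channel", {
  dir <- withr::local_tempdir()
  ny <- 8; nx <- 8
  g <- matrix(seq(0, 1, length.out = ny * nx), ny, nx)
  rgb <- array(0, c(ny, nx, 3))
  rgb[, , 1] <- g / 2          # red = G/2 so G = 2R
  rgb[, , 2] <- g
  for (t in 1:3) {
    png::writePNG(rgb, file.path(dir, sprintf("f%02d.png", t)))
  }
  cam <- camera_model("identity", deg_per_px = 1, max_code = 255)
  st <- load_frames(dir, cam, frame_rate = 50)
  expect_equal(dim(st$codes), c(ny, nx, 3))
  expect_equal(st$frame_rate, 50)
  expect_equal(st$codes[, , 1] / 255, g, tolerance = 1 / 255)

  # single-frame directory
  dir2 <- withr::local_tempdir()
  png::writePNG(g, file.path(dir2, "only.png"))
  expect_equal(dim(load_frames(dir2, cam)$codes)[3], 1)
})

test_that("load_frames rejects MP4, empty dirs and unequal frame sizes", {
  cam <- camera_model("identity", deg_per_px = 1)
  expect_error(load_frames("video.mp4", cam), "MP4")
  dir <- withr::local_tempdir()
  expect_error(load_frames(dir, cam), "no PNG")
  png::writePNG(matrix(0.5, 4, 4), file.path(dir, "a.png"))
  png::writePNG(matrix(0.5, 6, 6), file.path(dir, "b.png"))
  expect_error(load_frames(dir, cam), "unequal")
})

test_that("linearize applies monotone lookups and preserves entropy", {
  codes <- array(sample(0:255, 16 * 16 * 4, replace = TRUE), c(16, 16, 4))
  st <- make_stack(codes)
  # identity lookup
  cam_id <- camera_model("identity", deg_per_px = 1, max_code = 255)
  expect_equal(linearize(st, cam_id)$linear, codes)
  # square lookup: code 16 -> 256
  cam_sq <- camera_model("identity", deg_per_px = 1,
                         linearization = (0:255)^2, max_code = 255)
  expect_equal(linearize(st, cam_sq)$linear[codes == 16][1], 256)
  # entropy is invariant to any strictly monotone relabeling of codes
  s_raw <- video_sample(codes + 0, 1, 100, codes = codes)
  lin <- linearize(st, cam_sq)$linear
  s_lin <- video_sample(lin, 1, 100, codes = lin)
  expect_equal(contrast_entropy(s_raw), contrast_entropy(s_lin))
  # out-of-domain codes error
  expect_error(linearize(make_stack(codes - 1), cam_sq), "domain")
})

test_that("prefilter matches a directly evaluated gaussian kernel", {
  n <- 31
  imp <- array(0, c(n, n, 1)); imp[16, 16, 1] <- 1
  st <- prefilter(make_stack(imp), sigma_px = 2)
  got <- st$codes[, , 1]
  expect_equal(sum(got), 1, tolerance = 1e-10)
  expect_equal(got, brute_conv2(imp[, , 1], 2), tolerance = 1e-10)
  # constant frames unchanged; sigma 0 is the identity
  cst <- array(7, c(16, 16, 2))
  expect_equal(prefilter(make_stack(cst), 2)$codes, cst, tolerance = 1e-10)
  expect_identical(prefilter(make_stack(cst), 0)$codes, cst)
  expect_error(prefilter(make_stack(cst), -1), "sigma")
})

test_that("extraction yields duration * rate + 1 frames from the stream end", {
  cam <- camera_model("identity", deg_per_px = 0.5, max_code = 255)
  codes <- array(rep(1:30, each = 64 * 64), c(64, 64, 30))
  st <- linearize(make_stack(codes, frame_rate = 10), cam)
  sw <- sample_window(azimuth_center = 0, extent = 10, duration = 2,
                      output_resolution = 21)
  vs <- extract_sample(st, sw, cam)
  expect_equal(dim(vs$intensities), c(21, 21, 21))
  # final-2s window of a 3s stream: frames 10..30
  expect_equal(unique(as.vector(vs$intensities[, , 1])), 10)
  expect_equal(vs$deg_per_px * sw$output_resolution, sw$extent,
               tolerance = 1e-9)
  expect_error(extract_sample(st, sample_window(0, 0, 10, duration = 10,
                                                output_resolution = 21),
                              cam), "too short")
})

test_that("pinhole rectification is consistent with forward projection", {
  cam <- camera_model("pinhole", focal_px = 300, max_code = 255)
  # vertical bright edge in source pixel space at a known column
  codes <- array(0, c(600, 600, 9))
  codes[, 380:600, ] <- 200
  st <- linearize(make_stack(codes, frame_rate = 4), cam)
  sw <- sample_window(azimuth_center = 10, elevation_center = 0,
                      extent = 30, duration = 2, output_resolution = 61)
  vs <- extract_sample(st, sw, cam)
  # oracle: the edge at source column 380 corresponds to the tangent-plane
  # coordinate recovered by forward-projecting through the same camera
  az_edge <- atan((379.5 - 300.5) / 300)          # ray azimuth of the edge
  # output columns sample tan(angle) around the 10 deg centre
  ang <- seq(-15, 15, length.out = 61) * pi / 180
  col_expect <- which.min(abs(ang + 10 * pi / 180 - az_edge))
  mid <- vs$intensities[31, , 1]
  col_got <- which.max(diff(mid))
  expect_lt(abs(col_got - col_expect), 2)
})

test_that("rectified grid points project back within half a source pixel", {
  cam <- camera_model("equidistant-fisheye", focal_px = 250,
                      center_px = c(300, 300), max_code = 255)
  sw <- sample_window(azimuth_center = 38, elevation_center = 0,
                      extent = 75, duration = 1, output_resolution = 25)
  grid <- aquascene:::rectify_grid(sw, cam, c(600, 600))
  # forward project each sampled source location's ray again: the mapping
  # ray -> pixel -> (same ray) -> pixel must be a fixed point
  n <- sw$output_resolution
  theta <- sqrt((grid$px - 300)^2 + (grid$py - 300)^2) / 250
  phi <- atan2(grid$py - 300, grid$px - 300)
  rays <- cbind(as.vector(sin(theta) * cos(phi)),
                as.vector(-sin(theta) * sin(phi)),
                as.vector(cos(theta)))
  back <- aquascene:::project_rays(rays, cam, c(600, 600))
  expect_lt(max(abs(back[, 1] - as.vector(grid$px))), 0.5)
  expect_lt(max(abs(back[, 2] - as.vector(grid$py))), 0.5)
})

test_that("clipping rules flag bands and apply the inclusive 10% threshold", {
  cam <- camera_model("identity", deg_per_px = 1, max_code = 100)
  mid <- array(50, c(10, 10, 10))
  s_mid <- video_sample(mid, 1, 100, codes = mid)
  rep_mid <- clipping_check(s_mid, cam)
  expect_equal(rep_mid$low_fraction + rep_mid$high_fraction, 0)
  expect_false(rep_mid$excluded_sample)
  expect_false(any(rep_mid$clipped_mask))

  # exactly 12% saturated -> excluded
  codes <- array(50, c(10, 10, 10))
  codes[seq_len(120)] <- 100
  s12 <- video_sample(codes, 1, 100, codes = codes)
  r12 <- clipping_check(s12, cam)
  expect_equal(r12$high_fraction, 0.12)
  expect_true(r12$excluded_sample)

  # exactly 10% flagged -> excluded (boundary inclusive)
  codes10 <- array(50, c(10, 10, 10))
  codes10[seq_len(100)] <- 0
  r10 <- clipping_check(video_sample(codes10, 1, 100, codes = codes10), cam)
  expect_equal(r10$low_fraction, 0.10)
  expect_true(r10$excluded_sample)

  # surviving clipped pixels are masked out of contrast analyses
  codes5 <- array(50, c(10, 10, 10))
  codes5[seq_len(50)] <- 100
  s5 <- video_sample(codes5, 1, 100, codes = codes5)
  r5 <- clipping_check(s5, cam)
  expect_false(r5$excluded_sample)
  masked <- mask_clipped(s5, r5)
  expect_equal(sum(!masked$valid_mask), 50)
  expect_equal(contrast_moments(global_contrast(masked))$variance, 0)
})

test_that("mean intensity trace matches brute-force per-frame means", {
  s <- gaussian_sample(nx = 12, ny = 12, nt = 8)
  tr <- mean_intensity_trace(s)
  expect_equal(tr$mean_intensity,
               apply(s$intensities, 3, mean))
  # constant and ramp cases
  cst <- video_sample(array(3, c(8, 8, 4)), 1, 10)
  expect_equal(mean_intensity_trace(cst)$mean_intensity, rep(3, 4))
  ramp <- video_sample(array(rep(1:4, each = 64), c(8, 8, 4)), 1, 10)
  expect_equal(mean_intensity_trace(ramp)$mean_intensity, as.numeric(1:4))
  # fully masked frame yields NA
  m <- array(TRUE, c(8, 8, 4)); m[, , 2] <- FALSE
  s_m <- video_sample(array(1, c(8, 8, 4)), 1, 10, valid_mask = m)
  expect_true(is.na(mean_intensity_trace(s_m)$mean_intensity[2]))
})
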