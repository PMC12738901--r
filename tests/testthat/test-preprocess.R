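test_that("min-max normalisation maps range to [0,1] with the stated rules", {
  f <- matrix(c(2, 3, 4, 2), 2, 2)  # [[2,4],[3,2]] in row/col terms
  out <- normalize_minmax(f)
  expect_equal(out, matrix(c(0, 0.5, 1, 0), 2, 2))
  expect_equal(normalize_minmax(matrix(7, 3, 3)), matrix(0, 3, 3))
  # positive affine invariance, per frame
  set.seed(1)
  for (i in 1:5) {
    x <- array(runif(2 * 16 * 16), c(2, 16, 16))
    a <- runif(1, 0.5, 3); b <- runif(1, -2, 2)
    expect_equal(normalize_minmax(a * x + b), normalize_minmax(x),
                 tolerance = 1e-12)
  }
})

test_that("whole-video scope uses one global min/max", {
  x <- array(0, c(2, 2, 2))
  x[1, , ] <- 1; x[2, , ] <- c(0, 2, 2, 2)
  out <- normalize_minmax(x, scope = "video")
  expect_equal(out[1, 1, 1], 0.5)
  expect_equal(range(out), c(0, 1))
})

test_that("bleach correction removes smooth fields but keeps small structures", {
  expect_lt(max(abs(bleach_correct(matrix(3.3, 64, 64), sigma = 16))), 1e-6)
  # linear ramp: interior residual far below the gradient range
  ramp <- matrix(rep(seq(0, 1, length.out = 256), each = 256), 256, 256)
  res <- bleach_correct(ramp, sigma = 64)
  interior <- res[64:192, 64:192]
  expect_lt(max(abs(interior)), 0.05)
  # a 5-px blob keeps >= 90% of its contrast at sigma = 64
  f <- matrix(0.2, 256, 256)
  f[126:130, 126:130] <- 0.9
  bc <- bleach_correct(f, sigma = 64)
  contrast_kept <- (bc[128, 128] - stats::median(bc)) / 0.7
  expect_gte(contrast_kept, 0.9)
  expect_error(bleach_correct(ramp, sigma = 0), "sigma")
})

test_that("CLAHE keeps constants constant and does not reduce contrast", {
  const <- matrix(0.5, 100, 100)
  expect_equal(enhance_contrast_clahe(const), const)
  expect_equal(eval(formals(enhance_contrast_clahe)$kernel), 25)
  expect_equal(eval(formals(enhance_contrast_clahe)$clip), 0.01)
  expect_equal(eval(formals(enhance_contrast_clahe)$bins), 256)
  board <- matrix(rep(c(0.3, 0.6), length.out = 64 * 64), 64, 64)
  out <- enhance_contrast_clahe(board)
  expect_gte(diff(range(out)), diff(range(board)))
  expect_true(all(out >= 0 & out <= 1))
  expect_error(enhance_contrast_clahe(board * 3), "\\[0, 1\\]")
})

test_that("Gaussian smoothing is identity at sigma 0 and mass-preserving", {
  f <- matrix(runif(64 * 64), 64, 64)
  expect_identical(smooth_gaussian(f, 0), f)
  impulse <- matrix(0, 33, 33); impulse[17, 17] <- 1
  resp <- smooth_gaussian(impulse, 1)
  expect_lt(max(resp), 1)
  expect_equal(which.max(resp), 17 + 16 * 33)  # peak stays at the centre
  sm <- smooth_gaussian(f, 1)
  expect_lt(abs(mean(sm[8:56, 8:56]) - mean(f[8:56, 8:56])) /
              mean(f[8:56, 8:56]), 0.01)
  expect_error(smooth_gaussian(f, -1), "sigma")
})

test_that("the activity preprocessing chain has the stated order and range", {
  sc <- tiny_scenario(duration = 24, noise_sd = 0.01)
  sim <- render_video(sc)
  pre <- preprocess_for_activity(sim$video)
  expect_true(all(pre$frames >= 0 & pre$frames <= 1))
  expect_equal(pre$provenance$step,
               c("normalize_minmax", "bleach_correct", "normalize_minmax",
                 "enhance_contrast_clahe", "smooth_gaussian"))
  expect_equal(pre$provenance$scope[3], "video")
  one_frame <- video_stack(sim$video$frames[1, , ], 0.55, 4)
  expect_error(preprocess_for_activity(one_frame), "2 frames")
})

test_that("the chain is invariant to per-frame affine intensity rescaling", {
  sc <- tiny_scenario(duration = 16, noise_sd = 0.005)
  sim <- render_video(sc)
  pre1 <- preprocess_for_activity(sim$video)
  set.seed(4)
  scaled <- sim$video$frames
  for (i in seq_len(dim(scaled)[1])) {
    scaled[i, , ] <- scaled[i, , ] * runif(1, 0.5, 2) + runif(1, 0, 3)
  }
  pre2 <- preprocess_for_activity(video_stack(scaled, 0.55, 4))
  expect_equal(pre2$frames, pre1$frames, tolerance = 1e-8)
})

test_that("a x1.5 brightness drift is suppressed by the chain", {
  # static scene (no rounding events inside the window) so only drift varies
  sc <- tiny_scenario(n_cells = 9, field = c(192, 192), duration = 60,
                      rounding_time_mean = 900, drift_factor = 1.5,
                      noise_sd = 0.01, gradient_amplitude = 0.1)
  sim <- render_video(sc)
  raw_means <- apply(sim$video$frames, 1, mean)
  expect_gt(max(raw_means) / min(raw_means), 1.3)  # drift present in input
  pre <- preprocess_for_activity(sim$video)
  means <- apply(pre$frames, 1, mean)
  expect_lt((max(means) - min(means)) / mean(means), 0.10)
})

test_that("resampling realises the target pixel size and preserves extent", {
  v <- video_stack(array(runif(1200 * 1200), c(1, 1200, 1200)),
                   pixel_size = 0.55, frame_interval = 4)
  out <- resample_to_pixel_size(v, 0.865)
  expect_equal(dim(out$frames)[3], round(1200 * 0.55 / 0.865))  # 763
  expect_lt(abs(out$pixel_size - 0.865) / 0.865, 0.01)
  # physical extent preserved within one target pixel
  expect_lt(abs(dim(out$frames)[3] * out$pixel_size - 1200 * 0.55), 0.865)
  expect_identical(resample_to_pixel_size(v, 0.55), v)
  expect_error(resample_to_pixel_size(v, 0.4), "Upsampling")
})
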