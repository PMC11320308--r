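test_that("extraction takes the first sufficiently dark pixel in increasing y", {
  # 4 columns over y_axis -5..9; threshold 0.5
  D <- matrix(0, nrow = 4, ncol = 15)
  y_axis <- -5:9
  D[1, y_axis == 4] <- 0.9              # single dark pixel
  D[2, y_axis == -3] <- 0.6             # lower branch of a loop ...
  D[2, y_axis == 7] <- 1.0              # ... upper branch is ignored
  D[3, y_axis == 2] <- 0.3              # below threshold: fall back to max
  fl <- make_flat(D, y_axis = y_axis)
  prof <- extract_profile(fl, threshold = 0.5)
  expect_equal(prof$y[1:3], c(4, -3, 2))
  expect_equal(prof$n_original_pixels, 3L)

  expect_error(extract_profile(make_flat(matrix(0, 3, 3))), "no signal")
})

test_that("column 4 beyond the last ink is trimmed, interior gaps stay missing", {
  D <- matrix(0, nrow = 5, ncol = 4)
  D[1, 2] <- D[2, 2] <- D[4, 3] <- 1
  prof <- extract_profile(make_flat(D, y_axis = 0:3))
  expect_length(prof$y, 4L)        # columns 1..4 of the inked span
  expect_true(is.na(prof$y[3]))
  expect_equal(prof$n_original_pixels, 3L)
})

test_that("arc-length transform is the quadratic map s = b phi^2 / 2", {
  prof <- make_profile(phi = c(0, 1, 2, 3), y = c(1, 2, 3, 4), b = 2)
  prof <- to_arc_length(prof)
  expect_equal(prof$s, c(0, 1, 4, 9))
  expect_equal(prof$cropping_ratio, 1)
  # equal phi spacing stretches quadratically: s-gaps increase monotonically
  prof2 <- to_arc_length(make_profile(phi = seq(0.5, 6, by = 0.25),
                                      y = seq(0.5, 6, by = 0.25), b = 3))
  expect_true(all(diff(diff(prof2$s)) > 0))
})

test_that("noise-region cropping updates the cropping ratio multiplicatively", {
  prof <- to_arc_length(make_profile(phi = seq(0, 10, by = 0.1),
                                     y = sin(seq(0, 10, by = 0.1)), b = 2))
  same <- crop_noise_region(prof, 0)
  expect_equal(same$cropping_ratio, prof$cropping_ratio)
  expect_length(same$s, length(prof$s))

  # removing the first 10% of the extent scales the ratio by 0.9
  s_min <- 0.1 * max(prof$s)
  cropped <- crop_noise_region(prof, s_min)
  expect_equal(cropped$cropping_ratio,
               prof$cropping_ratio * (max(prof$s) - min(cropped$s)) /
                 diff(range(prof$s)))
  expect_equal(cropped$cropping_ratio, 0.9, tolerance = 0.01)

  expect_error(crop_noise_region(prof, max(prof$s) + 1), "empty signal")
})

test_that("resampling preserves an already-uniform profile up to normalization", {
  b <- 2
  s <- seq(1, 100, length.out = 200)
  y <- sin(s / 5) * 3 + 1
  prof <- to_arc_length(make_profile(phi = sqrt(2 * s / b), y = y, b = b))
  sig <- resample_and_normalize(prof, N = 200)
  yc <- y - mean(y)
  expect_equal(sig$y, yc * 1000 / max(abs(yc)), tolerance = 1e-6)
  expect_equal(sig$N, 200L)
})

test_that("normalization contract: zero mean, peak exactly 1000", {
  spec <- quick_spec(seed = 31)
  sig <- run_quick_pipeline(spec)$signal
  expect_equal(mean(sig$y), 0, tolerance = 1e-9)
  expect_equal(max(abs(sig$y)), 1000, tolerance = 1e-6)
  expect_equal(length(unique(sig$s)), sig$N)  # single-valued over s
  expect_true(all(diff(sig$s) > 0))
})

test_that("a constant profile cannot be normalized", {
  prof <- make_profile(phi = 0:10, y = rep(2, 11))
  expect_error(resample_and_normalize(prof, N = 10), "degenerate signal")
})

test_that("a sinusoidal profile has rms_raw = A / sqrt(2) within 1%", {
  A <- 17
  s <- seq(0, 500, length.out = 2000)
  y <- A * sin(2 * pi * 12 * s / 500)
  prof <- to_arc_length(make_profile(phi = sqrt(2 * s), y = y, b = 1))
  sig <- resample_and_normalize(prof, N = 1000)
  expect_equal(sig$rms_raw, A / sqrt(2), tolerance = 0.01)
  expect_equal(amplitude_rms(sig), sig$rms_raw)
})

test_that("amplitude_rms reports the stored pre-normalization RMS", {
  sig <- discrete_signal(s = 0:9, y = rep(0, 10), rms_raw = 0)
  expect_equal(amplitude_rms(sig), 0)
})

test_that("doubling the generated tremor amplitude doubles amplitude_rms", {
  a1 <- run_quick_pipeline(quick_spec(tremor_amplitude = 8, seed = 12))$signal
  a2 <- run_quick_pipeline(quick_spec(tremor_amplitude = 16, seed = 12))$signal
  expect_equal(amplitude_rms(a2) / amplitude_rms(a1), 2, tolerance = 0.05)
})

test_that("wide interior gaps raise an interpolation warning", {
  phi <- seq(0.5, 10, by = 0.05)
  y <- sin(phi)
  y[phi > 6 & phi < 8] <- NA  # a gap of ~28% of the s-extent
  prof <- make_profile(phi = phi, y = y)
  expect_warning(resample_and_normalize(prof, N = 100), "gap")
})

test_that("the extracted signal tracks the generated tremor (r >= 0.95)", {
  spec <- quick_spec(tremor_amplitude = 6, tremor_freq = 5,
                     stroke_width_hand = 4, seed = 13)
  res <- run_quick_pipeline(spec)
  sig <- res$signal
  d_true <- approx(res$truth$s, res$truth$d, xout = sig$s, rule = 2)$y
  expect_gte(cor(sig$y, d_true), 0.95)
})
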