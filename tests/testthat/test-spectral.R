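test_that("an N-sample real signal has N/2 + 1 coefficient pairs", {
  spec <- forward_fft(sin(seq_len(1000) / 7))
  expect_equal(spec$Ncoeff, 501L)
  expect_length(spec$magnitude, 501L)
  expect_length(spec$phase, 501L)
  expect_true(all(spec$magnitude >= 0))
  expect_error(forward_fft(rnorm(999)), "even")
})

test_that("inverse_fft inverts forward_fft to 1e-9", {
  set.seed(2)
  y <- rnorm(512)
  expect_equal(inverse_fft(forward_fft(y)), y, tolerance = 1e-9)
})

test_that("a constant signal concentrates all magnitude at k = 0", {
  spec <- forward_fft(rep(3.5, 64))
  expect_equal(spec$magnitude[1], 64 * 3.5)
  expect_equal(max(spec$magnitude[-1]), 0, tolerance = 1e-9)
  expect_equal(inverse_fft(spec), rep(3.5, 64), tolerance = 1e-12)
})

test_that("a pure cosine with 7 cycles excites only coefficient k = 7", {
  n <- 256
  y <- cos(2 * pi * 7 * (0:(n - 1)) / n)
  spec <- forward_fft(y)
  expect_equal(spec$magnitude[8], n / 2, tolerance = 1e-9)
  expect_lt(max(spec$magnitude[-8]), 1e-9 * n)
})

test_that("the low-pass filter zeroes k > floor(frac * Ncoeff)", {
  y <- rnorm(1000)
  spec <- forward_fft(y)
  lp <- low_pass(spec, 0.4)
  expect_equal(lp$lp_cutoff_index, 200L)  # floor(0.4 * 501)
  expect_equal(lp$magnitude[202:501], rep(0, 300))
  expect_equal(lp$magnitude[1:201], spec$magnitude[1:201])
  expect_lte(sum(lp$magnitude^2), sum(spec$magnitude^2))
  # frac = 1 is the identity
  expect_equal(low_pass(spec, 1)$magnitude, spec$magnitude)
})

test_that("truncation keeps the leading coefficients and is nested", {
  set.seed(3)
  sig <- rnorm(1000)
  spec <- forward_fft(sig)
  tr <- truncate_spectrum(spec, 150)
  expect_equal(tr$ntrunc, 150L)
  expect_equal(tr$magnitude[151:501], rep(0, 351))
  expect_equal(tr$magnitude[1:150], spec$magnitude[1:150])
  expect_equal(truncate_spectrum(spec, spec$Ncoeff)$magnitude, spec$magnitude)
  expect_error(truncate_spectrum(spec, 502), "ntrunc")
  expect_error(truncate_spectrum(spec, 0), "ntrunc")

  errs <- sapply(c(10, 50, 150, 300, 501), function(k) {
    rms_error_pct(sig, inverse_fft(truncate_spectrum(spec, k)))
  })
  expect_true(all(diff(errs) <= 1e-9))
  expect_equal(errs[5], 0, tolerance = 1e-9)
})

test_that("truncation is exact for band-limited signals", {
  n <- 1000
  t <- (0:(n - 1)) / n
  y <- 3 * sin(2 * pi * 40 * t) + cos(2 * pi * 120 * t)
  recon <- inverse_fft(truncate_spectrum(forward_fft(y), 150))
  expect_equal(recon, y, tolerance = 1e-9)
})

test_that("percent RMS error has the signal-RMS denominator", {
  a <- sin(seq(0, 20, length.out = 500))
  expect_equal(rms_error_pct(a, a), 0)
  expect_equal(rms_error_pct(a, 0.9 * a), 10, tolerance = 1e-9)
  expect_error(rms_error_pct(rep(0, 10), rnorm(10)), "zero RMS")

  # additive orthogonal noise of relative RMS 5%
  set.seed(4)
  n <- 4000
  t <- (0:(n - 1)) / n
  a <- sqrt(2) * sin(2 * pi * 9 * t)  # unit RMS
  e <- rnorm(n)
  e <- e - a * sum(e * a) / sum(a^2)  # orthogonalize
  e <- e * 0.05 / sqrt(mean(e^2))
  expect_equal(rms_error_pct(a, a + e), 5, tolerance = 0.02)
})

test_that("Parseval's identity holds for the one-sided spectrum", {
  set.seed(6)
  for (n in c(64, 1000)) {
    y <- rnorm(n)
    sp <- forward_fft(y)
    half <- n / 2
    power <- (sp$magnitude[1]^2 + sp$magnitude[half + 1]^2 +
                2 * sum(sp$magnitude[2:half]^2)) / n
    expect_equal(sum(y^2), power, tolerance = 1e-9)
  }
})

test_that("the reduction factor of a 3228-column drawing at 150 coefficients is 10.76", {
  expect_equal(reduction_factor(3228, 150), 10.76)
  sig <- discrete_signal(s = 0:9, y = rnorm(10), n_original_pixels = 3228)
  expect_equal(reduction_factor(sig, 150), 10.76)
})

test_that("Savitzky-Golay display smoothing is exact on cubics and leaves data untouched", {
  x <- seq(-2, 2, length.out = 201)
  p <- 0.5 * x^3 - x^2 + 2 * x + 1
  expect_equal(savgol_display(p), p, tolerance = 1e-6)
  expect_equal(savgol_display(rep(2, 101)), rep(2, 101), tolerance = 1e-9)
  expect_error(savgol_display(p, window = 50), "odd")
  expect_error(savgol_display(p, window = 5, polyorder = 7), "polyorder")

  spec <- forward_fft(rnorm(1000))
  mag_before <- spec$magnitude
  smoothed <- savgol_display(spec$magnitude)
  expect_identical(spec$magnitude, mag_before)
  expect_false(identical(smoothed, mag_before))
})

test_that("the truncated feature vector has 2*ntrunc + 1 entries", {
  sig <- discrete_signal(s = seq_len(1000), y = sin(seq_len(1000) / 9),
                         rms_raw = 4.2)
  fv <- feature_vector(truncate_spectrum(forward_fft(sig), 150), sig)
  expect_length(fv, 301L)
  expect_equal(unname(fv["rms_raw"]), 4.2)
})
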