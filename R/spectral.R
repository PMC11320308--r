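# Real-DFT analysis of the discrete signal: forward transform to
# magnitude/phase pairs, brick-wall low-pass, truncation to a small leading
# coefficient set, inverse reconstruction, and the percent RMS truncation
# error. For an even N-sample real signal the one-sided spectrum has
# Ncoeff = N/2 + 1 coefficients (indices k = 0 .. N/2).

#' Magnitude/phase spectrum of a real discrete signal
#'
#' @param magnitude Non-negative magnitudes, `Ncoeff = N/2 + 1` values.
#' @param phase Phases in `(-pi, pi]`, same length.
#' @param N Source sample count (even).
#' @param lp_cutoff_index Highest retained coefficient index (0-based) after
#'   low-pass filtering, or `NULL`.
#' @param ntrunc Retained-coefficient count after truncation, or `NULL`.
#' @return An object of class `"spectral_result"` with field
#'   `Ncoeff = N/2 + 1`.
#' @export
spectral_result <- function(magnitude, phase, N, lp_cutoff_index = NULL,
                            ntrunc = NULL) {
  stopifnot(N %% 2L == 0L, length(magnitude) == N / 2 + 1,
            length(phase) == length(magnitude), all(magnitude >= 0))
  structure(list(magnitude = magnitude, phase = phase,
                 N = as.integer(N), Ncoeff = as.integer(N / 2 + 1),
                 lp_cutoff_index = lp_cutoff_index, ntrunc = ntrunc),
            class = "spectral_result")
}

#' @export
print.spectral_result <- function(x, ...) {
  cat(sprintf("real-DFT spectrum: Ncoeff = %d (N = %d)", x$Ncoeff, x$N))
  if (!is.null(x$lp_cutoff_index))
    cat(sprintf(", low-pass at k = %d", x$lp_cutoff_index))
  if (!is.null(x$ntrunc))
    cat(sprintf(", truncated to %d coefficients", x$ntrunc))
  cat("\n")
  invisible(x)
}

#' Forward real DFT of a discrete signal
#'
#' Computes the FFT of the real-valued signal and keeps the one-sided
#' magnitude and phase, `Ncoeff = N/2 + 1` coefficient pairs
#' (for N = 1000 samples, 501 coefficients).
#'
#' @param sig A [discrete_signal()] or numeric vector with even length
#'   `>= 4`.
#' @return A [spectral_result()].
#' @export
forward_fft <- function(sig) {
  y <- if (inherits(sig, "discrete_signal")) sig$y else sig
  stopifnot(is.numeric(y))
  N <- length(y)
  if (N < 4L || N %% 2L != 0L) {
    stop("forward_fft requires an even sample count N >= 4 (the resampler always emits even N)",
         call. = FALSE)
  }
  z <- stats::fft(y)[1:(N / 2 + 1)]
  spectral_result(Mod(z), Arg(z), N)
}

#' Brick-wall low-pass filter in the coefficient domain
#'
#' Zeroes every coefficient with index `k > floor(frac * Ncoeff)` (magnitude
#' and phase), eliminating high-frequency noise outside the tremor band. The
#' default cutoff fraction is 0.4, i.e. k > 200 for N = 1000.
#'
#' @param spec A [spectral_result()].
#' @param frac Cutoff fraction in `(0, 1]` (default 0.4).
#' @return The filtered [spectral_result()] with `lp_cutoff_index` recorded.
#' @export
low_pass <- function(spec, frac = 0.4) {
  stopifnot(inherits(spec, "spectral_result"), frac > 0, frac <= 1)
  cutoff <- floor(frac * spec$Ncoeff)  # 0-based index bound
  drop <- seq_len(spec$Ncoeff) - 1L > cutoff
  spec$magnitude[drop] <- 0
  spec$phase[drop] <- 0
  spec$lp_cutoff_index <- as.integer(min(cutoff, spec$Ncoeff - 1L))
  spec
}

#' Truncate the spectrum to its leading coefficients
#'
#' Keeps the first `ntrunc` magnitude/phase pairs and zeroes the remainder,
#' giving a representation of `2 * ntrunc` parameters (both magnitude and
#' phase are needed to recover the signal).
#'
#' @param spec A [spectral_result()].
#' @param ntrunc Retained-coefficient count in `[1, Ncoeff]` (default 150).
#' @return The truncated [spectral_result()] with `ntrunc` recorded.
#' @export
truncate_spectrum <- function(spec, ntrunc = 150L) {
  stopifnot(inherits(spec, "spectral_result"))
  if (ntrunc < 1L || ntrunc > spec$Ncoeff) {
    stop("ntrunc must lie in [1, Ncoeff]", call. = FALSE)
  }
  drop <- seq_len(spec$Ncoeff) > ntrunc
  spec$magnitude[drop] <- 0
  spec$phase[drop] <- 0
  spec$ntrunc <- as.integer(ntrunc)
  spec
}

#' Inverse real DFT
#'
#' Rebuilds the full Hermitian spectrum from the one-sided magnitude/phase
#' pairs and returns the length-N real signal. For an untruncated spectrum
#' this inverts [forward_fft()] to machine precision.
#'
#' @param spec A [spectral_result()].
#' @return Numeric vector of length `spec$N`.
#' @export
inverse_fft <- function(spec) {
  stopifnot(inherits(spec, "spectral_result"))
  N <- spec$N
  half <- N / 2L
  z <- spec$magnitude * exp(1i * spec$phase)
  full <- complex(N)
  full[1:(half + 1L)] <- z
  full[(half + 2L):N] <- Conj(z[half:2])
  Re(stats::fft(full, inverse = TRUE)) / N
}

#' Percent RMS error between a signal and its reconstruction
#'
#' `100 * RMS(a - b) / RMS(a)`, with `a` the untruncated reference signal.
#' The signal-RMS denominator makes the percentage invariant under the fixed
#' +/-1000 normalization.
#'
#' @param a Reference signal ([discrete_signal()] or numeric vector).
#' @param b Comparison signal of equal length.
#' @return Percent RMS error.
#' @export
rms_error_pct <- function(a, b) {
  av <- if (inherits(a, "discrete_signal")) a$y else a
  bv <- if (inherits(b, "discrete_signal")) b$y else b
  stopifnot(is.numeric(av), is.numeric(bv), length(av) == length(bv))
  denom <- sqrt(mean(av^2))
  if (denom == 0) {
    stop("undefined error: reference signal has zero RMS", call. = FALSE)
  }
  100 * sqrt(mean((av - bv)^2)) / denom
}

#' Parameter-reduction factor of the truncated representation
#'
#' Ratio of the original pixel-column count to the `2 * ntrunc` coefficients
#' of the truncated magnitude/phase representation (e.g. 3228 original
#' pixel columns over 300 coefficients give 10.76).
#'
#' @param n_original_pixels Original x-pixel count, or a [discrete_signal()]
#'   whose `n_original_pixels` field is used.
#' @param ntrunc Retained-coefficient count (default 150).
#' @return Dimensionless reduction factor.
#' @export
reduction_factor <- function(n_original_pixels, ntrunc = 150L) {
  n <- if (inherits(n_original_pixels, "discrete_signal")) {
    n_original_pixels$n_original_pixels
  } else {
    n_original_pixels
  }
  stopifnot(is.numeric(n), n > 0, ntrunc >= 1)
  n / (2 * ntrunc)
}

#' Savitzky-Golay smoothing for spectrum display
#'
#' Returns a smoothed copy of the magnitude spectrum for plotting only
#' (window 51, polynomial order 3 by default); the analysed data are never
#' altered.
#'
#' @param magnitude Numeric magnitude vector (longer than `window`).
#' @param window Odd filter window length (default 51).
#' @param polyorder Polynomial order, less than `window` (default 3).
#' @return Smoothed magnitude vector of the same length.
#' @export
savgol_display <- function(magnitude, window = 51L, polyorder = 3L) {
  stopifnot(is.numeric(magnitude))
  if (window %% 2L != 1L || polyorder >= window || polyorder < 0) {
    stop("invalid Savitzky-Golay parameters: window must be odd and polyorder < window",
         call. = FALSE)
  }
  if (length(magnitude) <= window) {
    stop("magnitude vector must be longer than the filter window", call. = FALSE)
  }
  as.numeric(signal::sgolayfilt(magnitude, p = polyorder, n = window))
}

#' Truncated FFT feature vector
#'
#' Concatenates the first `ntrunc` magnitudes, the first `ntrunc` phases,
#' and the pre-normalization RMS amplitude — `2 * ntrunc + 1` features, the
#' compact representation intended for downstream statistical models.
#'
#' @param spec A truncated [spectral_result()] (see [truncate_spectrum()]).
#' @param sig The source [discrete_signal()] (provides `rms_raw`).
#' @return Named numeric vector of length `2 * spec$ntrunc + 1`.
#' @export
feature_vector <- function(spec, sig) {
  stopifnot(inherits(spec, "spectral_result"), !is.null(spec$ntrunc),
            inherits(sig, "discrete_signal"))
  k <- seq_len(spec$ntrunc)
  stats::setNames(c(spec$magnitude[k], spec$phase[k], sig$rms_raw),
                  c(paste0("mag_", k - 1L), paste0("phase_", k - 1L), "rms_raw"))
}
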