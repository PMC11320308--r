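# Labelling the coefficient axis in Hz and locating the tremor peak.
#
# A spatially drawn spiral carries no time base of its own; given the
# wall-clock drawing time T and assuming a constant arc-length drawing rate,
# the retained record spans T * cropping_ratio seconds, so coefficient k
# maps to f_k = k / (T * cropping_ratio) Hz — the standard DFT bin width for
# that effective duration. Clinically relevant tremor lies below ~12 Hz.

#' Frequency axis for a spectrum
#'
#' @param spec A [spectral_result()].
#' @param t_to_draw Drawing time in seconds, positive.
#' @param cropping_ratio Retained fraction of the record in `(0, 1]`
#'   (default 1).
#' @param band_of_interest Tremor search band `(low, high)` in Hz
#'   (default `c(1, 12)`; the 1 Hz floor keeps slow drawing drift out of the
#'   peak search, the 12 Hz ceiling is the upper end of clinical tremor).
#' @return An object of class `"frequency_axis"` with `hz_per_index` and the
#'   per-coefficient `frequencies`.
#' @export
build_axis <- function(spec, t_to_draw, cropping_ratio = 1,
                       band_of_interest = c(1, 12)) {
  stopifnot(inherits(spec, "spectral_result"))
  if (is.null(t_to_draw) || is.na(t_to_draw) || t_to_draw <= 0) {
    stop("metrics unavailable: a positive drawing time t_to_draw is required to express the axis in Hz",
         call. = FALSE)
  }
  stopifnot(cropping_ratio > 0, cropping_ratio <= 1 + 1e-12,
            length(band_of_interest) == 2L,
            band_of_interest[1] < band_of_interest[2])
  hz <- 1 / (t_to_draw * cropping_ratio)
  structure(list(hz_per_index = hz, t_to_draw = t_to_draw,
                 cropping_ratio = cropping_ratio,
                 band_of_interest = band_of_interest,
                 frequencies = (seq_len(spec$Ncoeff) - 1L) * hz),
            class = "frequency_axis")
}

#' Tremor-peak frequency
#'
#' Returns the frequency of the maximum-magnitude coefficient within the
#' axis's band of interest. Ties resolve to the lower frequency.
#'
#' @param spec A [spectral_result()].
#' @param axis A [build_axis()] result for the same spectrum.
#' @return Peak frequency in Hz, with attributes `index` (0-based
#'   coefficient index) and `magnitude`.
#' @export
peak_frequency <- function(spec, axis) {
  stopifnot(inherits(spec, "spectral_result"), inherits(axis, "frequency_axis"))
  f <- axis$frequencies
  if (length(f) != spec$Ncoeff) {
    stop("axis and spectrum disagree on the coefficient count", call. = FALSE)
  }
  sel <- which(f >= axis$band_of_interest[1] & f <= axis$band_of_interest[2])
  if (length(sel) == 0L) {
    stop("band of interest not covered by the frequency axis", call. = FALSE)
  }
  mag <- spec$magnitude[sel]
  if (all(mag == 0)) {
    stop("no peak: spectrum is zero throughout the band of interest", call. = FALSE)
  }
  i <- sel[which.max(mag)]  # which.max returns the first (lowest-f) maximum
  structure(f[i], index = i - 1L, magnitude = spec$magnitude[i])
}

#' Tremor metrics report
#'
#' Convenience bundle of the quantities a clinical reading needs: peak
#' frequency and magnitude, RMS amplitude in pixels, truncation settings and
#' truncation error, and the band edges.
#'
#' @param sig A [discrete_signal()] with `rms_raw` recorded.
#' @param spec The (low-passed, untruncated) [spectral_result()] of `sig`.
#' @param axis A [build_axis()] result, or `NULL` to report the peak in
#'   coefficient units.
#' @param ntrunc Truncation count used for the error figure (default 150).
#' @return A named list (class `"tremor_metrics"`).
#' @export
tremor_metrics <- function(sig, spec, axis = NULL, ntrunc = 150L) {
  stopifnot(inherits(sig, "discrete_signal"), inherits(spec, "spectral_result"))
  recon <- inverse_fft(truncate_spectrum(spec, ntrunc))
  err <- rms_error_pct(sig$y, recon)
  if (is.null(axis)) {
    sel <- 2:spec$Ncoeff
    i <- sel[which.max(spec$magnitude[sel])]
    pk <- list(frequency_hz = NA_real_, index = i - 1L,
               magnitude = spec$magnitude[i], band_hz = c(NA_real_, NA_real_))
  } else {
    p <- peak_frequency(spec, axis)
    pk <- list(frequency_hz = as.numeric(p), index = attr(p, "index"),
               magnitude = attr(p, "magnitude"),
               band_hz = axis$band_of_interest)
  }
  structure(c(pk, list(amplitude_rms_px = amplitude_rms(sig),
                       ntrunc = as.integer(ntrunc),
                       rms_error_pct = err,
                       cropping_ratio = sig$cropping_ratio,
                       t_to_draw = sig$t_to_draw)),
            class = "tremor_metrics")
}

#' @export
print.tremor_metrics <- function(x, ...) {
  if (is.na(x$frequency_hz)) {
    cat(sprintf("tremor peak: coefficient k = %d (no drawing time; Hz unavailable)\n",
                x$index))
  } else {
    cat(sprintf("tremor peak: %.2f Hz (k = %d) in band [%g, %g] Hz\n",
                x$frequency_hz, x$index, x$band_hz[1], x$band_hz[2]))
  }
  cat(sprintf("amplitude (RMS): %.2f px; truncation to %d coefficients: %.2f%% RMS error\n",
              x$amplitude_rms_px, x$ntrunc, x$rms_error_pct))
  invisible(x)
}
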