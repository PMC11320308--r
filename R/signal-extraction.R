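# From the cropped single-band flattened image to a single-valued, uniformly
# sampled, normalized discrete signal over arc length.
#
# Extraction is threshold-first-hit: each x-column is scanned in increasing y
# and the first cell at or above the density threshold wins. On loops this
# latches onto the lower branch of a multi-valued curve, which is the
# documented behaviour of the method; columns where nothing reaches the
# threshold fall back to the column's density maximum, and truly empty
# columns are marked missing and later filled by linear interpolation.

#' Uniformly sampled deviation signal over arc length
#'
#' @param s Arc-length sample positions (pixels), strictly increasing,
#'   uniform.
#' @param y Deviation values. After [resample_and_normalize()] these have
#'   zero mean and `max(abs(y)) == 1000`.
#' @param cropping_ratio Fraction of the originally extracted arc-length
#'   extent retained after all crops, in `(0, 1]`; scales the Hz axis.
#' @param rms_raw RMS of the mean-removed deviation before normalization,
#'   in source pixels — the tremor-amplitude measure.
#' @param n_original_pixels Number of non-missing x-columns in the
#'   pre-resampling extraction.
#' @param t_to_draw Optional drawing time in seconds.
#' @param params Optional [spiral_params()] carried along for provenance.
#' @return An object of class `"discrete_signal"` with field `N` equal to
#'   `length(s)`.
#' @export
discrete_signal <- function(s, y, cropping_ratio = 1, rms_raw = NA_real_,
                            n_original_pixels = length(s), t_to_draw = NULL,
                            params = NULL) {
  stopifnot(is.numeric(s), is.numeric(y), length(s) == length(y),
            length(s) >= 2L)
  if (!is.null(cropping_ratio) &&
      (cropping_ratio <= 0 || cropping_ratio > 1 + 1e-12)) {
    stop("cropping_ratio must lie in (0, 1]", call. = FALSE)
  }
  structure(list(s = as.numeric(s), y = as.numeric(y), N = length(s),
                 cropping_ratio = cropping_ratio, rms_raw = rms_raw,
                 n_original_pixels = n_original_pixels,
                 t_to_draw = t_to_draw, params = params),
            class = "discrete_signal")
}

#' @export
print.discrete_signal <- function(x, ...) {
  cat(sprintf("discrete signal: N = %d samples, s in [%.1f, %.1f] px\n",
              x$N, min(x$s), max(x$s)))
  cat(sprintf("  cropping_ratio = %.4f, rms_raw = %.3f px%s\n",
              x$cropping_ratio, x$rms_raw,
              if (is.null(x$t_to_draw)) "" else
                sprintf(", t_to_draw = %.1f s", x$t_to_draw)))
  invisible(x)
}

#' Extract the raw single-valued profile from a flattened band
#'
#' For each x-column the rows are scanned in increasing y and the first cell
#' whose density reaches `threshold` gives the column's y-value (so on a
#' closed loop the lower branch is kept). Columns with no cell at the
#' threshold fall back to the y of the column's maximum density when that
#' maximum is positive; otherwise the column is missing. Leading and
#' trailing missing columns are trimmed.
#'
#' @param fimg A (typically cropped) flattened image.
#' @param threshold Density threshold in `[0, 1]` (default 0.5).
#' @return An object of class `"spiral_profile"`: flattened abscissae `phi`
#'   (radians), deviations `y` (flattened y-units; `NA` where missing),
#'   `n_original_pixels`, and the spiral parameters.
#' @export
extract_profile <- function(fimg, threshold = 0.5) {
  stopifnot(inherits(fimg, "flattened_image"),
            threshold > 0, threshold <= 1)
  D <- fimg$density
  above <- 1 * (D >= threshold)
  hit <- max.col(above, ties.method = "first")
  hit[rowSums(above) == 0] <- NA_integer_
  fb <- which(is.na(hit))
  if (length(fb)) {
    mx <- max.col(D[fb, , drop = FALSE], ties.method = "first")
    pos <- D[cbind(fb, mx)] > 0
    hit[fb[pos]] <- mx[pos]
  }
  if (all(is.na(hit))) {
    stop("no signal: every column of the flattened band is empty", call. = FALSE)
  }
  span <- range(which(!is.na(hit)))
  idx <- span[1]:span[2]
  structure(list(phi = fimg$x_axis[idx] / fimg$alpha,
                 y = ifelse(is.na(hit[idx]), NA_real_, fimg$y_axis[hit[idx]]),
                 n_original_pixels = sum(!is.na(hit[idx])),
                 params = fimg$params, beta = fimg$beta,
                 s = NULL, cropping_ratio = NA_real_),
            class = "spiral_profile")
}

#' Transform a profile's abscissa to arc length
#'
#' Applies `s = b * phi^2 / 2` to every column (a monotone map, so ordering
#' is preserved; uniform phi-spacing becomes quadratically stretched
#' s-spacing). Also initializes the cropping ratio as
#' `(s_max - s_min) / s_max`: the record nominally starts at the `x = 0`
#' edge, so any missing lead-in counts as already cropped.
#'
#' @param profile A `"spiral_profile"` from [extract_profile()].
#' @return The profile with fields `s` and `cropping_ratio` set.
#' @export
to_arc_length <- function(profile) {
  stopifnot(inherits(profile, "spiral_profile"))
  profile$s <- arc_length(profile$params, profile$phi)
  s_hi <- max(profile$s)
  if (s_hi <= 0) stop("no signal: profile has zero arc-length extent", call. = FALSE)
  profile$cropping_ratio <- (s_hi - min(profile$s)) / s_hi
  profile
}

#' Crop the near-origin noise region from a profile
#'
#' The first fraction of arc length can carry noise spikes (mis-zoned pixels
#' near the spiral centre); samples with `s < s_min` are removed and the
#' removed fraction is folded into the cropping ratio.
#'
#' @param profile A `"spiral_profile"` with arc length set
#'   (see [to_arc_length()]).
#' @param s_min Arc-length lower bound in pixels, non-negative.
#' @return The cropped profile.
#' @export
crop_noise_region <- function(profile, s_min) {
  stopifnot(inherits(profile, "spiral_profile"), s_min >= 0)
  if (is.null(profile$s)) profile <- to_arc_length(profile)
  keep <- profile$s >= s_min
  if (!any(keep)) {
    stop("empty signal: s_min is beyond the last sample", call. = FALSE)
  }
  ext0 <- diff(range(profile$s))
  profile$phi <- profile$phi[keep]
  profile$s <- profile$s[keep]
  profile$y <- profile$y[keep]
  profile$n_original_pixels <- sum(!is.na(profile$y))
  ext1 <- diff(range(profile$s))
  if (ext1 <= 0) stop("empty signal: cropped profile has no extent", call. = FALSE)
  profile$cropping_ratio <- profile$cropping_ratio * ext1 / ext0
  profile
}

#' Resample to N uniform arc-length samples and normalize
#'
#' Missing columns are filled by linear interpolation between their
#' neighbours (a warning is raised when an interior gap exceeds
#' `max_gap_frac` of the extent), the profile is linearly interpolated onto
#' `N` uniform arc-length points spanning its extent, deviations are
#' converted to source pixels, the mean is removed (recording `rms_raw`),
#' and the result is scaled so that `max(abs(y))` is exactly 1000.
#'
#' @param profile A `"spiral_profile"`.
#' @param N Sample count, even, at least 4 (default 1000).
#' @param max_gap_frac Interior-gap warning threshold as a fraction of the
#'   arc-length extent (default 0.05).
#' @return A [discrete_signal()].
#' @export
resample_and_normalize <- function(profile, N = 1000L, max_gap_frac = 0.05) {
  stopifnot(inherits(profile, "spiral_profile"),
            N >= 4L, N %% 2L == 0L)
  if (is.null(profile$s)) profile <- to_arc_length(profile)
  ok <- !is.na(profile$y)
  if (sum(ok) < 2L) {
    stop("no signal: fewer than two non-missing samples", call. = FALSE)
  }
  s <- profile$s
  ext <- diff(range(s))
  if (any(!ok)) {
    # arc-length spans bridged across missing columns
    gaps <- diff(s[ok])[diff(which(ok)) > 1L]
    if (length(gaps) && any(gaps > max_gap_frac * ext)) {
      warning(sprintf("interior gap of %.1f%% of the extent filled by linear interpolation",
                      100 * max(gaps) / ext), call. = FALSE)
    }
  }
  yf <- stats::approx(s[ok], profile$y[ok], xout = s, rule = 2)$y
  s_u <- seq(min(s), max(s), length.out = N)
  y_u <- stats::approx(s, yf, xout = s_u)$y / profile$beta  # source pixels
  yc <- y_u - mean(y_u)
  peak <- max(abs(yc))
  if (peak == 0) {
    stop("degenerate signal: deviation profile is constant", call. = FALSE)
  }
  discrete_signal(s = s_u, y = yc * (1000 / peak),
                  cropping_ratio = profile$cropping_ratio,
                  rms_raw = sqrt(mean(yc^2)),
                  n_original_pixels = profile$n_original_pixels,
                  params = profile$params)
}

#' RMS tremor amplitude in pixels
#'
#' The pre-normalization, mean-removed RMS of the deviation signal, in
#' source-pixel units. This is the amplitude measure that survives the fixed
#' +/-1000 normalization and is appended to the truncated feature vector.
#'
#' @param sig A [discrete_signal()].
#' @return RMS amplitude in pixels.
#' @export
amplitude_rms <- function(sig) {
  stopifnot(inherits(sig, "discrete_signal"))
  if (is.na(sig$rms_raw)) {
    stop("rms_raw was not recorded for this signal", call. = FALSE)
  }
  sig$rms_raw
}
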