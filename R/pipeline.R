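# Non-interactive pipeline driver. The interactive point/rectangle clicks of
# a GUI workflow are externalized into a run configuration (JSON/YAML or a
# plain list), so a full run is deterministic and scriptable:
#   fit -> flatten -> crop -> extract -> resample/normalize -> save   (extract)
#   FFT -> low-pass -> truncate -> inverse -> RMS error -> features   (spectrum)
#   Hz axis -> tremor peak -> amplitude                               (metrics)
# A thin command-line front-end lives at inst/cli/spiraltrace.

#' Assemble and validate a run configuration
#'
#' @param config A named list, or a path to a JSON or YAML file containing
#'   one. Required fields: `image_path` (unless the image is passed to
#'   [run_extract()] directly), `origin` (x, y), `fit_point_1` and
#'   `fit_point_2` (each a list/vector with `x`, `y` and optional `zone`;
#'   zones default to 1 and 2). Optional fields with defaults:
#'   `crop_rect` (`list(x = c(lo, hi), y = c(lo, hi))` in flattened units),
#'   `s_min` (0), `N` (1000), `ntrunc` (150), `lp_frac` (0.4),
#'   `threshold` (0.5), `contrast_stretch` (FALSE), `t_to_draw` (NULL),
#'   `output_dir` ("."), `seed` (1).
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    ext <- tolower(tools::file_ext(config))
    config <- if (ext %in% c("yml", "yaml")) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("YAML configs require the yaml package; use JSON instead",
             call. = FALSE)
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  stopifnot(is.list(config))
  for (field in c("origin", "fit_point_1", "fit_point_2")) {
    if (is.null(config[[field]])) {
      stop("invalid config: missing required field '", field, "'",
           call. = FALSE)
    }
  }
  as_point <- function(p, default_zone) {
    p <- as.list(unlist(p))
    if (is.null(names(p)) || !all(c("x", "y") %in% names(p))) {
      names(p)[1:2] <- c("x", "y")
    }
    list(x = as.numeric(p$x), y = as.numeric(p$y),
         zone = as.integer(p$zone %||% default_zone))
  }
  cfg <- list(
    image_path = config$image_path,
    origin = as.numeric(unlist(config$origin)),
    fit_point_1 = as_point(config$fit_point_1, 1L),
    fit_point_2 = as_point(config$fit_point_2, 2L),
    crop_rect = config$crop_rect,
    s_min = as.numeric(config$s_min %||% 0),
    N = as.integer(config$N %||% 1000L),
    ntrunc = as.integer(config$ntrunc %||% 150L),
    lp_frac = as.numeric(config$lp_frac %||% 0.4),
    threshold = as.numeric(config$threshold %||% 0.5),
    contrast_stretch = isTRUE(config$contrast_stretch),
    t_to_draw = config$t_to_draw,
    output_dir = config$output_dir %||% ".",
    seed = as.integer(config$seed %||% 1L))
  if (length(cfg$origin) != 2L) {
    stop("invalid config: 'origin' must be (x, y)", call. = FALSE)
  }
  if (cfg$N %% 2L != 0L) {
    stop("invalid config: N must be even", call. = FALSE)
  }
  if (cfg$ntrunc < 1L || cfg$ntrunc > cfg$N / 2L + 1L) {
    stop("invalid config: ntrunc must lie in [1, N/2 + 1]", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Run the extraction pipeline: image to discrete signal
#'
#' Fits the spiral from the two configured points, flattens the image via
#' the zone-family mapping, crops to the configured rectangle, extracts the
#' single-valued profile, converts to arc length, crops the near-origin
#' noise region, resamples to N samples and normalizes. The signal is saved
#' as `signal.csv` (+ JSON sidecar) in `output_dir`, the flattened band as
#' `flattened.png`, and every step is logged to `run.log`.
#'
#' @param config A [run_config()] (or anything it accepts).
#' @param image Optional [ink_image()]; when given, `image_path` is ignored.
#' @param write Write output files (default `TRUE`).
#' @return The [discrete_signal()], invisibly.
#' @export
run_extract <- function(config, image = NULL, write = TRUE) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  if (is.null(image) && is.null(cfg$image_path)) {
    stop("invalid config: no image and no image_path given", call. = FALSE)
  }
  if (write) dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(cfg$output_dir, "run.log")
  log_step <- function(msg) if (write) append_log(logf, msg)

  img <- image %||% read_image(cfg$image_path, cfg$contrast_stretch)
  log_step(sprintf("step 1-1: read image (%d x %d px)", img$width, img$height))

  p1 <- polar_from_cartesian(c(cfg$fit_point_1$x, cfg$fit_point_1$y), cfg$origin)
  p2 <- polar_from_cartesian(c(cfg$fit_point_2$x, cfg$fit_point_2$y), cfg$origin)
  params <- fit_from_two_points(p1, p2,
                                zones = c(cfg$fit_point_1$zone,
                                          cfg$fit_point_2$zone),
                                origin = cfg$origin)
  log_step(sprintf("step 1-2: fitted spiral b = %.4f px/rad, theta_r = %.4f rad",
                   params$b, params$theta_r))

  fimg <- flatten_image(img, params)
  log_step(sprintf("step 1-3: flattened image (%d x %d cells)",
                   nrow(fimg$density), ncol(fimg$density)))

  if (!is.null(cfg$crop_rect)) {
    fimg <- crop_rect(fimg,
                      x_range = as.numeric(unlist(cfg$crop_rect$x)),
                      y_range = as.numeric(unlist(cfg$crop_rect$y)))
  }
  log_step("step 1-4: cropped to a single stitched hand drawing")

  prof <- extract_profile(fimg, threshold = cfg$threshold)
  prof <- to_arc_length(prof)
  if (cfg$s_min > 0) prof <- crop_noise_region(prof, cfg$s_min)
  sig <- resample_and_normalize(prof, N = cfg$N)
  sig$t_to_draw <- cfg$t_to_draw
  log_step(sprintf("step 1-5: derived signal (N = %d, cropping_ratio = %.4f, rms_raw = %.2f px)",
                   sig$N, sig$cropping_ratio, sig$rms_raw))
  if (write) {
    write_signal_csv(sig, file.path(cfg$output_dir, "signal.csv"))
    grey <- 1 - fimg$density
    png::writePNG(t(pmin(pmax(grey, 0), 1))[rev(seq_len(ncol(fimg$density))), ,
                                            drop = FALSE],
                  file.path(cfg$output_dir, "flattened.png"))
  }
  invisible(sig)
}

#' Run the spectral pipeline: discrete signal to truncated FFT report
#'
#' Reads the signal (CSV path or [discrete_signal()]), computes the real
#' FFT, applies the low-pass filter, truncates, reconstructs via the inverse
#' FFT and evaluates the percent RMS truncation error; the truncated feature
#' vector (`2 * ntrunc` magnitude/phase coefficients plus `rms_raw`) is part
#' of the report.
#'
#' @param signal A [discrete_signal()] or path to a CSV from
#'   [write_signal_csv()].
#' @param ntrunc Truncation count (default 150).
#' @param lp_frac Low-pass cutoff fraction (default 0.4).
#' @param output_dir Optional directory: writes `features.csv` and
#'   `spectrum_report.json`.
#' @return List (class `"spectrum_report"`) with `spectrum` (low-passed),
#'   `truncated`, `reconstruction`, `rms_error_pct`, `features`,
#'   `n_features`, `reduction_factor`.
#' @export
run_spectrum <- function(signal, ntrunc = 150L, lp_frac = 0.4,
                         output_dir = NULL) {
  sig <- if (is.character(signal)) read_signal_csv(signal) else signal
  stopifnot(inherits(sig, "discrete_signal"))
  if (ntrunc < 1L || ntrunc > sig$N / 2L + 1L) {
    stop("invalid config: ntrunc must lie in [1, Ncoeff]", call. = FALSE)
  }
  spec <- low_pass(forward_fft(sig), frac = lp_frac)
  trunc <- truncate_spectrum(spec, ntrunc)
  recon <- inverse_fft(trunc)
  feats <- feature_vector(trunc, sig)
  report <- structure(
    list(spectrum = spec, truncated = trunc, reconstruction = recon,
         rms_error_pct = rms_error_pct(sig$y, recon),
         features = feats, n_features = length(feats),
         reduction_factor = reduction_factor(sig, ntrunc)),
    class = "spectrum_report")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(data.frame(feature = names(feats), value = feats),
                     file.path(output_dir, "features.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(N = sig$N, ncoeff = spec$Ncoeff, ntrunc = ntrunc,
           lp_cutoff_index = spec$lp_cutoff_index,
           rms_error_pct = report$rms_error_pct,
           reduction_factor = report$reduction_factor,
           n_features = report$n_features),
      file.path(output_dir, "spectrum_report.json"),
      auto_unbox = TRUE, digits = NA)
  }
  report
}

#' Run the metrics pipeline: tremor frequency and amplitude
#'
#' Builds the Hz axis from the drawing time and cropping ratio, locates the
#' tremor peak in the band of interest and reports the RMS amplitude. When
#' no drawing time is available the peak is reported in coefficient units
#' with a warning.
#'
#' @param signal A [discrete_signal()] or CSV path.
#' @param t_to_draw Drawing time in seconds; default: the value stored with
#'   the signal.
#' @param band Tremor search band in Hz (default `c(1, 12)`).
#' @param lp_frac Low-pass cutoff fraction applied before the peak search.
#' @param ntrunc Truncation count for the error figure (default 150).
#' @param output_dir Optional directory: writes `metrics.json`.
#' @return A [tremor_metrics()] report.
#' @export
run_metrics <- function(signal, t_to_draw = NULL, band = c(1, 12),
                        lp_frac = 0.4, ntrunc = 150L, output_dir = NULL) {
  sig <- if (is.character(signal)) read_signal_csv(signal) else signal
  stopifnot(inherits(sig, "discrete_signal"))
  t_to_draw <- t_to_draw %||% sig$t_to_draw
  spec <- low_pass(forward_fft(sig), frac = lp_frac)
  axis <- NULL
  if (is.null(t_to_draw) || is.na(t_to_draw %||% NA)) {
    warning("no drawing time recorded; reporting the peak in coefficient units",
            call. = FALSE)
  } else {
    axis <- build_axis(spec, t_to_draw, sig$cropping_ratio,
                       band_of_interest = band)
  }
  m <- tremor_metrics(sig, spec, axis, ntrunc = ntrunc)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(m), file.path(output_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  m
}

#' Run the simulator: generate a synthetic cohort on disk
#'
#' @param n Cohort size (default 18).
#' @param seed RNG seed (default 1).
#' @param output_dir Output directory for PNG images, JSON truth sidecars
#'   and the manifest CSV.
#' @return The cohort list from [make_cohort()], invisibly.
#' @export
run_simulate <- function(n = 18L, seed = 1L, output_dir = "cohort") {
  invisible(make_cohort(n = n, seed = seed, dir = output_dir))
}

# Ground-truth helpers shared by the validation harness -----------------------

# Two on-curve fit points at config precision (the pipeline takes its
# coordinates from a config file, not from screen clicks):
# theta = pi in zone one, theta = 3 pi in zone two.
truth_fit_points <- function(truth) {
  p <- truth$params
  xy1 <- p$origin + spiral_xy(p, pi)[1, ]
  xy2 <- p$origin + spiral_xy(p, 3 * pi)[1, ]
  list(fit_point_1 = list(x = xy1[1], y = xy1[2], zone = 1L),
       fit_point_2 = list(x = xy2[1], y = xy2[2], zone = 2L))
}

# Crop rectangle isolating the stitched hand-drawing band: the drawing sits
# hand_offset above the reference band, so +/- 0.7 * pi * b around it keeps
# the tremor excursions and excludes all other stitched families.
truth_crop_rect <- function(truth, b) {
  list(x = c(0, truth$phi_end + 0.5),
       y = truth$hand_offset + c(-0.7, 0.7) * pi * b)
}

# Full pipeline on one synthetic drawing using its ground truth for the
# click coordinates and crop rectangle.
pipeline_on_sample <- function(sample, N = 1000L, s_min_frac = 0.02,
                               threshold = 0.5) {
  truth <- sample$truth
  fp <- truth_fit_points(truth)
  cfg <- run_config(c(list(origin = truth$params$origin,
                           s_min = s_min_frac * truth$s_total,
                           N = N, threshold = threshold,
                           t_to_draw = truth$t_to_draw),
                      fp))
  p1 <- polar_from_cartesian(c(cfg$fit_point_1$x, cfg$fit_point_1$y), cfg$origin)
  p2 <- polar_from_cartesian(c(cfg$fit_point_2$x, cfg$fit_point_2$y), cfg$origin)
  params <- fit_from_two_points(p1, p2, origin = cfg$origin)
  fimg <- flatten_image(sample$image, params)
  cr <- truth_crop_rect(truth, params$b)
  fimg <- crop_rect(fimg, x_range = cr$x, y_range = cr$y)
  prof <- to_arc_length(extract_profile(fimg, threshold = threshold))
  prof <- crop_noise_region(prof, cfg$s_min)
  sig <- resample_and_normalize(prof, N = N)
  sig$t_to_draw <- truth$t_to_draw
  list(signal = sig, params = params, truth = truth)
}

#' Evaluate the full pipeline over a synthetic cohort
#'
#' Generates (or accepts) a cohort, runs fit, flattening, extraction and
#' spectral truncation on every sample using the ground-truth click
#' coordinates and crop rectangles, and tabulates per-sample results: the
#' percent RMS truncation error, the recovered tremor frequency against the
#' ground truth, the RMS amplitude against the expected `A / sqrt(2)`, and
#' the fitted spiral parameters against the generating ones.
#'
#' @param n Cohort size (default 18).
#' @param seed RNG seed (default 1).
#' @param ntrunc Truncation count (default 150).
#' @param lp_frac Low-pass cutoff fraction (default 0.4).
#' @param cohort Optional pre-generated cohort from [make_cohort()].
#' @return A data frame with one row per sample.
#' @export
evaluate_cohort <- function(n = 18L, seed = 1L, ntrunc = 150L, lp_frac = 0.4,
                            cohort = NULL) {
  cohort <- cohort %||% make_cohort(n = n, seed = seed)
  rows <- lapply(seq_along(cohort), function(i) {
    res <- pipeline_on_sample(cohort[[i]])
    sig <- res$signal
    rep <- run_spectrum(sig, ntrunc = ntrunc, lp_frac = lp_frac)
    axis <- build_axis(rep$spectrum, sig$t_to_draw, sig$cropping_ratio)
    pk <- tryCatch(peak_frequency(rep$spectrum, axis),
                   error = function(e) NA_real_)
    truth <- res$truth
    data.frame(sample = sprintf("S%d", i),
               rms_error_pct = rep$rms_error_pct,
               peak_hz = as.numeric(pk),
               f_true = truth$tremor_freq,
               bin_hz = axis$hz_per_index,
               amplitude_rms = amplitude_rms(sig),
               amplitude_expected = truth$tremor_amplitude / sqrt(2),
               b_fit = res$params$b, b_true = truth$params$b,
               theta_r_fit = res$params$theta_r,
               theta_r_true = truth$params$theta_r,
               cropping_ratio = sig$cropping_ratio,
               n_original_pixels = sig$n_original_pixels)
  })
  do.call(rbind, rows)
}
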