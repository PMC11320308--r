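# Raster input, ink-density conversion, and all file outputs (CSV signal +
# JSON sidecar, plain-text event log, PNG dumps). Internally every image is
# an ink-density matrix indexed [x, y] in y-up orientation, with density 1 =
# fully dark ink and 0 = white paper (the inversion of the raw grey scale).

#' Ink-density image
#'
#' @param density Numeric matrix of ink densities in `[0, 1]`, indexed
#'   `[x, y]` with y increasing upwards. Density 1 is fully dark ink,
#'   0 is white background.
#' @param source_path Provenance string (file path or `"synthetic"`).
#' @return An object of class `"ink_image"` with fields `density`, `width`,
#'   `height`, `source_path`.
#' @export
ink_image <- function(density, source_path = NA_character_) {
  stopifnot(is.matrix(density), is.numeric(density))
  if (anyNA(density) || min(density) < 0 || max(density) > 1) {
    stop("ink densities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(density = density, width = nrow(density),
                 height = ncol(density), source_path = source_path),
            class = "ink_image")
}

#' @export
print.ink_image <- function(x, ...) {
  cat(sprintf("ink image: %d x %d px, max density %.3f (%s)\n",
              x$width, x$height, max(x$density),
              if (is.na(x$source_path)) "in memory" else x$source_path))
  invisible(x)
}

rec601_luminance <- function(arr) {
  if (length(dim(arr)) == 2L) return(arr)
  # drop alpha if present; Rec. 601 weights for RGB
  0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
}

stretch_density <- function(d) {
  q <- stats::quantile(d, c(0.01, 0.99), names = FALSE)
  if (q[2] <= q[1]) return(d)
  pmin(pmax((d - q[1]) / (q[2] - q[1]), 0), 1)
}

read_jpeg_grey <- function(path) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop("JPEG input requires the EBImage package; alternatively convert to PNG or TIFF: ",
         path, call. = FALSE)
  }
  arr <- EBImage::imageData(EBImage::readImage(path))
  # EBImage stores [x, y(, channel)] with y increasing downward
  if (length(dim(arr)) == 3L) {
    arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
  }
  t(arr)  # -> [row, col], row 1 at top, like png::readPNG
}

#' Read a raster image as an ink-density image
#'
#' Decodes an 8-bit greyscale or RGB raster (PNG, TIFF, or JPEG via EBImage),
#' converts colour to luminance (Rec. 601 weights), inverts grey to ink
#' density (`density = 1 - grey/255` for 8-bit data), and flips the row order
#' so that all internal mathematics is y-up. With `contrast_stretch = TRUE`
#' densities are linearly rescaled so the 1st/99th percentiles map to 0/1
#' (clipped) — useful for suppressing the light-grey background that
#' photocopying and scanning introduce.
#'
#' @param path Path to a PNG, TIFF or JPEG file.
#' @param contrast_stretch Apply percentile contrast enhancement
#'   (default `FALSE`).
#' @return An [ink_image()].
#' @export
read_image <- function(path, contrast_stretch = FALSE) {
  if (!file.exists(path)) {
    stop("cannot read image: file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = read_jpeg_grey(path),
    stop("unsupported image format '", ext, "': ", path, call. = FALSE))
  grey <- rec601_luminance(raw)
  if (!is.matrix(grey)) grey <- as.matrix(grey)
  dens <- 1 - grey
  dens <- t(dens[nrow(dens):1, , drop = FALSE])  # [x, y], y-up
  dens <- pmin(pmax(dens, 0), 1)
  if (contrast_stretch) dens <- stretch_density(dens)
  ink_image(dens, source_path = path)
}

#' Write an ink-density image to a PNG file
#'
#' Inverse of the read convention: grey = 1 - density, rows flipped back to
#' top-down order.
#'
#' @param img An [ink_image()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  stopifnot(inherits(img, "ink_image"))
  grey <- 1 - t(img$density)
  grey <- grey[nrow(grey):1, , drop = FALSE]
  png::writePNG(pmin(pmax(grey, 0), 1), target = path)
  invisible(path)
}

signal_sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Save a discrete signal as CSV with a JSON metadata sidecar
#'
#' The CSV has a `s,y` header and one row per sample (arc length in pixels,
#' deviation in normalized pixel units). The sidecar
#' (`<path without extension>.json`) carries the sample count, cropping
#' ratio, pre-normalization RMS, original pixel-column count, drawing time
#' and the fitted spiral parameters, so downstream spectral analysis can run
#' from the files alone.
#'
#' @param sig A [discrete_signal()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(sig, path) {
  stopifnot(inherits(sig, "discrete_signal"))
  utils::write.csv(data.frame(s = sig$s, y = sig$y), path,
                   row.names = FALSE, quote = FALSE)
  meta <- list(N = sig$N,
               cropping_ratio = sig$cropping_ratio,
               rms_raw = sig$rms_raw,
               n_original_pixels = sig$n_original_pixels,
               t_to_draw = sig$t_to_draw)
  if (!is.null(sig$params)) {
    meta$params <- list(b = sig$params$b, theta_r = sig$params$theta_r,
                        origin = sig$params$origin)
  }
  jsonlite::write_json(meta, signal_sidecar_path(path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a discrete signal saved by [write_signal_csv()]
#'
#' @param path CSV path; the JSON sidecar is read from the same stem when
#'   present.
#' @return A [discrete_signal()].
#' @export
read_signal_csv <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read signal: file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path)
  if (!all(c("s", "y") %in% names(df))) {
    stop("malformed signal CSV (expected columns 's' and 'y'): ", path,
         call. = FALSE)
  }
  meta <- list()
  sp <- signal_sidecar_path(path)
  if (file.exists(sp)) meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  params <- NULL
  if (!is.null(meta$params)) {
    params <- spiral_params(meta$params$b, meta$params$theta_r,
                            unlist(meta$params$origin))
  }
  discrete_signal(s = df$s, y = df$y,
                  cropping_ratio = meta$cropping_ratio %||% 1,
                  rms_raw = meta$rms_raw %||% NA_real_,
                  n_original_pixels = meta$n_original_pixels %||% nrow(df),
                  t_to_draw = meta$t_to_draw,
                  params = params)
}

#' Append a timestamped event to a run log
#'
#' @param logfile Path to the plain-text log file (created if absent).
#' @param event Non-empty message string.
#' @return `logfile`, invisibly.
#' @export
append_log <- function(logfile, event) {
  if (!is.character(event) || length(event) != 1L || !nzchar(trimws(event))) {
    stop("log event must be a non-empty string", call. = FALSE)
  }
  line <- paste(format(Sys.time(), "%Y-%m-%d %H:%M:%OS3"), event)
  cat(line, "\n", file = logfile, sep = "", append = TRUE)
  invisible(logfile)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
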