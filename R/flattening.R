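# Zone-family mapping into Flattened Space. Each ink pixel at polar
# coordinates (r, theta') is mapped once per candidate turn index n to
#   x = alpha * (theta' + 2*pi*(n-1) + theta_r)
#   y = beta  * (r - b * (theta' + 2*pi*(n-1) + theta_r))
# so that segments of the reference spiral self-stitch into horizontal bands
# with vertical spacing 2*pi*b, and the hand drawing self-stitches into a
# family of parallel curves. The target raster is engineering choice: the
# mapping itself defines no grid, so mapped points deposit into the nearest
# cell with max-aggregation (preserving darkest-ink semantics downstream).

#' Configuration of the flattening transform
#'
#' @param alpha,beta Positive x/y scale constants of the flattening map
#'   (default 1, without loss of generality).
#' @param n_list Strictly increasing positive turn indices used for the
#'   family mapping (default `1:4`, matching a four-turn template).
#' @param density_floor Minimum ink density for a source pixel to be mapped
#'   (default 0.1); background pixels below it are skipped.
#' @param x_pitch Flattened-grid column spacing in radians. Default `NULL`
#'   chooses `1 / mean(r)` over the mapped pixels, i.e. roughly one source
#'   pixel of arc at the average ring radius per column.
#' @param y_pitch Flattened-grid row spacing in pixels (default 1 source
#'   pixel).
#' @return An object of class `"flatten_config"`.
#' @export
flatten_config <- function(alpha = 1, beta = 1, n_list = 1:4,
                           density_floor = 0.1, x_pitch = NULL, y_pitch = 1) {
  stopifnot(alpha > 0, beta > 0, length(n_list) >= 1L,
            all(n_list == as.integer(n_list)), all(n_list > 0),
            all(diff(n_list) > 0),
            density_floor >= 0, density_floor < 1,
            is.null(x_pitch) || x_pitch > 0, y_pitch > 0)
  structure(list(alpha = alpha, beta = beta, n_list = as.integer(n_list),
                 density_floor = density_floor, x_pitch = x_pitch,
                 y_pitch = y_pitch),
            class = "flatten_config")
}

#' Map a single polar point to its family of flattened points
#'
#' @param p A [polar_point()] with `theta` interpreted as the wrapped angle
#'   `theta'` in `[0, 2*pi)`.
#' @param params A [spiral_params()].
#' @param cfg A [flatten_config()].
#' @return Matrix with columns `x`, `y`, one row per entry of `cfg$n_list`.
#'   Consecutive rows differ by exactly `(2*pi*alpha, -2*pi*b*beta)`.
#' @export
flatten_point <- function(p, params, cfg = flatten_config()) {
  stopifnot(inherits(p, "polar_point"), inherits(params, "spiral_params"))
  phi <- p$theta + 2 * pi * (cfg$n_list - 1) + params$theta_r
  cbind(x = cfg$alpha * phi,
        y = cfg$beta * (p$r - params$b * phi))
}

flattened_image <- function(density, x_axis, y_axis, params, alpha, beta,
                            x_retained = NULL) {
  structure(list(density = density, x_axis = x_axis, y_axis = y_axis,
                 params = params, alpha = alpha, beta = beta,
                 x_retained = x_retained),
            class = "flattened_image")
}

#' @export
print.flattened_image <- function(x, ...) {
  cat(sprintf("flattened image: %d x %d cells, x in [%.3f, %.3f] rad, y in [%.1f, %.1f] px\n",
              nrow(x$density), ncol(x$density),
              min(x$x_axis), max(x$x_axis), min(x$y_axis), max(x$y_axis)))
  invisible(x)
}

#' @export
plot.flattened_image <- function(x, ...) {
  graphics::image(x$x_axis, x$y_axis, x$density,
                  col = grDevices::grey(seq(1, 0, length.out = 64)),
                  xlab = expression(theta + theta[r] ~ "(rad)"),
                  ylab = expression(r - b * (theta + theta[r]) ~ "(px)"), ...)
}

#' Flatten a spiral image via the zone-family mapping
#'
#' Every source pixel whose ink density reaches `cfg$density_floor` is mapped
#' through [flatten_point()] for every turn index in `cfg$n_list`; each
#' mapped point deposits its density into the nearest flattened-grid cell
#' (cell value = max of deposited densities). Only the half-plane `x >= 0`
#' is kept.
#'
#' @param img An [ink_image()].
#' @param params The fitted [spiral_params()].
#' @param cfg A [flatten_config()].
#' @return A `"flattened_image"`: density grid plus strictly increasing,
#'   uniformly pitched `x_axis` (radians) and `y_axis` (pixels), and the
#'   `params` used.
#' @export
flatten_image <- function(img, params, cfg = flatten_config()) {
  stopifnot(inherits(img, "ink_image"), inherits(params, "spiral_params"))
  D <- img$density
  sel <- which(D >= max(cfg$density_floor, 1e-12))
  if (length(sel) == 0L) {
    stop("empty image: no pixel reaches the density floor", call. = FALSE)
  }
  W <- nrow(D)
  px <- ((sel - 1L) %% W) + 1L
  py <- ((sel - 1L) %/% W) + 1L
  dx <- px - params$origin[1]
  dy <- py - params$origin[2]
  r <- sqrt(dx^2 + dy^2)
  keep <- r > 0
  if (!any(keep)) stop("empty image: only the origin pixel is inked", call. = FALSE)
  r <- r[keep]
  thp <- atan2(dy[keep], dx[keep]) %% (2 * pi)
  dens <- D[sel][keep]

  nn <- cfg$n_list
  m <- length(r)
  phi <- rep(thp, times = length(nn)) +
    rep(2 * pi * (nn - 1) + params$theta_r, each = m)
  fx <- cfg$alpha * phi
  fy <- cfg$beta * (rep(r, times = length(nn)) - params$b * phi)
  fd <- rep(dens, times = length(nn))
  ok <- fx >= 0
  if (!any(ok)) stop("empty image: no mapped point falls at x >= 0", call. = FALSE)
  fx <- fx[ok]; fy <- fy[ok]; fd <- fd[ok]

  x_pitch <- cfg$x_pitch %||% (1 / mean(r))
  y_pitch <- cfg$y_pitch
  ci <- as.integer(round(fx / x_pitch)) + 1L
  y0 <- min(fy)
  ri <- as.integer(round((fy - y0) / y_pitch)) + 1L
  M <- matrix(0, nrow = max(ci), ncol = max(ri))
  o <- order(fd)  # ascending, so the largest density wins the cell
  M[cbind(ci[o], ri[o])] <- fd[o]
  flattened_image(M,
                  x_axis = (seq_len(nrow(M)) - 1L) * x_pitch,
                  y_axis = y0 + (seq_len(ncol(M)) - 1L) * y_pitch,
                  params = params, alpha = cfg$alpha, beta = cfg$beta)
}

#' Crop a rectangle out of a flattened image
#'
#' Selects the sub-grid whose axis values fall inside `x_range` and
#' `y_range`, preserving the axes. The retained x-extent is recorded in the
#' result (`x_retained`) for bookkeeping. A warning is raised when the crop
#' excludes the `x = 0` edge, because the arc-length origin (and hence the
#' cropping-ratio accounting for the frequency axis) is anchored there.
#'
#' @param fimg A flattened image from [flatten_image()].
#' @param x_range,y_range Length-2 numeric ranges in flattened units
#'   (radians / pixels); `NULL` keeps the full extent.
#' @return A cropped `"flattened_image"`.
#' @export
crop_rect <- function(fimg, x_range = NULL, y_range = NULL) {
  stopifnot(inherits(fimg, "flattened_image"))
  x_range <- x_range %||% range(fimg$x_axis)
  y_range <- y_range %||% range(fimg$y_axis)
  xi <- which(fimg$x_axis >= min(x_range) & fimg$x_axis <= max(x_range))
  yi <- which(fimg$y_axis >= min(y_range) & fimg$y_axis <= max(y_range))
  if (length(xi) == 0L || length(yi) == 0L) {
    stop("crop error: rectangle does not intersect the flattened grid",
         call. = FALSE)
  }
  x_pitch <- if (length(fimg$x_axis) > 1L) diff(fimg$x_axis[1:2]) else 1
  if (min(fimg$x_axis[xi]) > x_pitch / 2) {
    warning("crop excludes the x = 0 edge; arc-length bookkeeping will treat the first retained column as the record start",
            call. = FALSE)
  }
  flattened_image(fimg$density[xi, yi, drop = FALSE],
                  x_axis = fimg$x_axis[xi], y_axis = fimg$y_axis[yi],
                  params = fimg$params, alpha = fimg$alpha, beta = fimg$beta,
                  x_retained = range(fimg$x_axis[xi]))
}
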