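# Closed-form Archimedes-spiral mathematics: representation, two-point fit,
# point evaluation and arc length. All angles are in radians, measured
# counter-clockwise from the positive x-axis in mathematical (y-up)
# orientation; image row order (y-down) is converted at the I/O boundary.

#' Archimedes spiral parameters
#'
#' Bundles the fitted parameters of the reference spiral
#' \eqn{r = b(\theta + \theta_r)}: the scale `b` (pixels per radian, strictly
#' positive), the rotation angle `theta_r` (radians), and the pixel
#' coordinates of the spiral centre.
#'
#' @param b Spiral scale in pixels per radian; must be positive (choosing
#'   `b > 0` makes the spiral wind counter-clockwise with growing radius).
#' @param theta_r Rotation angle in radians. Points with `r > 0` satisfy
#'   `theta > -theta_r`.
#' @param origin Numeric length-2 vector `(x0, y0)`: image-pixel coordinates
#'   of the spiral centre (y-up convention).
#'
#' @return An object of class `"spiral_params"`.
#' @seealso [fit_from_two_points()], [spiral_radius()], [spiral_xy()]
#' @export
#' @examples
#' spiral_params(b = 2, theta_r = 0.5, origin = c(300, 300))
spiral_params <- function(b, theta_r, origin = c(0, 0)) {
  stopifnot(is.numeric(b), length(b) == 1L, is.finite(b),
            is.numeric(theta_r), length(theta_r) == 1L, is.finite(theta_r),
            is.numeric(origin), length(origin) == 2L, all(is.finite(origin)))
  if (b <= 0) {
    stop("spiral scale 'b' must be positive", call. = FALSE)
  }
  structure(list(b = as.numeric(b), theta_r = as.numeric(theta_r),
                 origin = as.numeric(origin)),
            class = "spiral_params")
}

#' @export
print.spiral_params <- function(x, ...) {
  cat(sprintf("Archimedes spiral: r = %.6g * (theta + %.6g)\n", x$b, x$theta_r))
  cat(sprintf("  origin: (%.2f, %.2f) px (y-up)\n", x$origin[1], x$origin[2]))
  invisible(x)
}

#' Polar point relative to the spiral origin
#'
#' @param r Radius in pixels, non-negative.
#' @param theta Angle in radians.
#' @return An object of class `"polar_point"` with fields `r` and `theta`.
#' @export
polar_point <- function(r, theta) {
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r),
            is.numeric(theta), length(theta) == 1L, is.finite(theta))
  if (r < 0) stop("radius must be non-negative", call. = FALSE)
  structure(list(r = as.numeric(r), theta = as.numeric(theta)),
            class = "polar_point")
}

#' Convert a pixel coordinate to polar form about the spiral origin
#'
#' Inverts `x = r cos(theta), y = r sin(theta)` for a point expressed in the
#' image's y-up pixel frame. The returned angle lies in `[0, 2*pi)`.
#'
#' @param point Numeric length-2 pixel coordinate `(x, y)`.
#' @param origin Numeric length-2 pixel coordinate of the spiral centre.
#' @return A [polar_point()].
#' @export
#' @examples
#' polar_from_cartesian(c(105, 100), origin = c(100, 100))  # r = 5, theta = 0
polar_from_cartesian <- function(point, origin) {
  stopifnot(is.numeric(point), length(point) == 2L,
            is.numeric(origin), length(origin) == 2L)
  dx <- point[1] - origin[1]
  dy <- point[2] - origin[2]
  r <- sqrt(dx^2 + dy^2)
  if (r == 0) {
    stop("degenerate point: coincides with the spiral origin", call. = FALSE)
  }
  polar_point(r, atan2(dy, dx) %% (2 * pi))
}

#' Fit the spiral from two on-spiral points
#'
#' Solves the two-point system for the rotation and scale of
#' \eqn{r = b(\theta + \theta_r)}:
#' \deqn{\theta_r = \frac{r_2\theta_1 - r_1\theta_2}{r_1 - r_2}, \qquad
#'       b = \frac{r_1 - r_2}{\theta_1 - \theta_2},}
#' where each angle is first unwrapped by its zone (turn) index,
#' `theta = theta' + 2*pi*(zone - zone_offset)` with `theta'` in `[0, 2*pi)`.
#' By convention the first user-selected point lies in zone one (no angular
#' offset) and the second in zone two (one full turn).
#'
#' @param p1,p2 [polar_point()]s measured about the chosen origin.
#' @param zones Integer pair of zone indices for `p1` and `p2`
#'   (default `c(1, 2)`).
#' @param zone_offset Zone index that carries zero angular offset (default 1,
#'   so zone one keeps `theta = theta'`).
#' @param origin Pixel coordinates stored in the result (default `c(0, 0)`).
#' @return A [spiral_params()] with `b > 0`.
#' @export
#' @examples
#' p1 <- polar_point(r = pi, theta = pi)        # zone 1
#' p2 <- polar_point(r = 3 * pi, theta = pi)    # zone 2 (unwraps to 3*pi)
#' fit_from_two_points(p1, p2)                  # b = 1, theta_r = 0
fit_from_two_points <- function(p1, p2, zones = c(1L, 2L), zone_offset = 1L,
                                origin = c(0, 0)) {
  stopifnot(inherits(p1, "polar_point"), inherits(p2, "polar_point"),
            length(zones) == 2L, zones[1] >= zone_offset - 1L)
  th1 <- p1$theta + 2 * pi * (zones[1] - zone_offset)
  th2 <- p2$theta + 2 * pi * (zones[2] - zone_offset)
  if (p1$r == p2$r || th1 == th2) {
    stop("degenerate fit: the two points must have distinct radii and distinct unwrapped angles",
         call. = FALSE)
  }
  theta_r <- (p2$r * th1 - p1$r * th2) / (p1$r - p2$r)
  b <- (p1$r - p2$r) / (th1 - th2)
  if (b <= 0) {
    stop("invalid selection: fitted spiral scale b <= 0; check point order and zone assignment",
         call. = FALSE)
  }
  spiral_params(b, theta_r, origin)
}

#' Spiral radius at an angle
#'
#' Evaluates `r = b * (theta + theta_r)`. Vectorized over `theta`.
#'
#' @param params A [spiral_params()].
#' @param theta Unwrapped angle(s), radians; must satisfy `theta > -theta_r`.
#' @return Radius in pixels.
#' @export
spiral_radius <- function(params, theta) {
  stopifnot(inherits(params, "spiral_params"), is.numeric(theta))
  if (any(theta <= -params$theta_r)) {
    stop("out of domain: theta must exceed -theta_r", call. = FALSE)
  }
  params$b * (theta + params$theta_r)
}

#' Spiral point in Cartesian coordinates relative to the origin
#'
#' Evaluates `x = b(theta + theta_r) cos(theta)`,
#' `y = b(theta + theta_r) sin(theta)`. Vectorized over `theta`.
#'
#' @inheritParams spiral_radius
#' @return A two-column matrix with columns `x` and `y` (pixels, relative to
#'   the spiral origin).
#' @export
spiral_xy <- function(params, theta) {
  r <- spiral_radius(params, theta)
  cbind(x = r * cos(theta), y = r * sin(theta))
}

#' Arc length along the spiral
#'
#' Integrating `ds = r dtheta` along `r = b(theta + theta_r)` gives
#' `s = b * phi^2 / 2` in terms of the flattened abscissa
#' `phi = theta + theta_r` (which starts at 0 at the spiral centre).
#' Vectorized over `phi`.
#'
#' @param params A [spiral_params()].
#' @param phi Flattened abscissa `theta + theta_r`, radians; non-negative.
#' @return Arc length in pixels, strictly increasing in `phi`.
#' @export
#' @examples
#' arc_length(spiral_params(3, 0), phi = 4)  # 24
arc_length <- function(params, phi) {
  stopifnot(inherits(params, "spiral_params"), is.numeric(phi))
  if (any(phi < 0)) {
    stop("out of domain: phi must be non-negative", call. = FALSE)
  }
  0.5 * params$b * phi^2
}
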