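# Synthetic spiral drawings with known ground truth. The generator emulates
# the artifacts of scanned clinical drawings: a reference spiral at an
# arbitrary rotation, a hand drawing with a radial sinusoidal tremor drawn at
# constant arc-length rate in the space between the reference turns,
# multi-pixel stroke widths with grey-value jitter, a light-grey background,
# and optional gaps, closed loops, crossings of the reference curve and a
# near-origin ink spike.

with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Specification of a synthetic spiral drawing
#'
#' @param image_size Square image side in pixels (default 600).
#' @param turns Reference-spiral revolutions (default 4).
#' @param b Spiral scale in px/rad; default scales the outermost turn to 45%
#'   of the image size.
#' @param theta_r Rotation angle of the reference spiral, radians.
#' @param origin Spiral centre in pixels (default: image centre).
#' @param stroke_width_ref,stroke_width_hand Stroke widths in pixels
#'   (>= 1).
#' @param tremor_amplitude Radial tremor amplitude A in pixels (>= 0).
#' @param tremor_freq Tremor frequency f in Hz (>= 0).
#' @param t_to_draw Drawing time in seconds (> 0); with the constant
#'   arc-length drawing rate this links arc length to time.
#' @param phase Tremor phase in radians.
#' @param hand_offset Radial offset of the hand drawing from the reference
#'   curve, pixels; default `pi * b`, i.e. midway between the reference
#'   turns, where patients are asked to draw.
#' @param background_grey Background ink density in `[0, 1)` emulating a
#'   light-grey scan background (default 0.05).
#' @param grey_jitter Relative stroke-intensity variation in `[0, 1)`
#'   (default 0.15), emulating varying pen pressure and scan grey values.
#' @param artifacts Named logical list; any of `gaps`, `loops`, `crossings`,
#'   `origin_spike` (all default `FALSE`).
#' @param seed RNG seed controlling jitter and artifact placement.
#' @return An object of class `"simulation_spec"` whose `params` field holds
#'   the ground-truth [spiral_params()].
#' @export
simulation_spec <- function(image_size = 600L, turns = 4, b = NULL,
                            theta_r = 0.8, origin = NULL,
                            stroke_width_ref = 3, stroke_width_hand = 3,
                            tremor_amplitude = 10, tremor_freq = 5,
                            t_to_draw = 10, phase = 0, hand_offset = NULL,
                            background_grey = 0.05, grey_jitter = 0.15,
                            artifacts = list(), seed = 1L) {
  b <- b %||% (0.45 * image_size / (2 * pi * turns))
  origin <- origin %||% c((image_size + 1) / 2, (image_size + 1) / 2)
  hand_offset <- hand_offset %||% (pi * b)
  stopifnot(image_size >= 64, turns >= 1,
            stroke_width_ref >= 1, stroke_width_hand >= 1,
            tremor_amplitude >= 0, tremor_freq >= 0, t_to_draw > 0,
            background_grey >= 0, background_grey < 1,
            grey_jitter >= 0, grey_jitter < 1)
  art <- utils::modifyList(list(gaps = FALSE, loops = FALSE,
                                crossings = FALSE, origin_spike = FALSE),
                           as.list(artifacts))
  structure(list(image_size = as.integer(image_size), turns = turns,
                 params = spiral_params(b, theta_r, origin),
                 stroke_width_ref = stroke_width_ref,
                 stroke_width_hand = stroke_width_hand,
                 tremor_amplitude = tremor_amplitude,
                 tremor_freq = tremor_freq, t_to_draw = t_to_draw,
                 phase = phase, hand_offset = hand_offset,
                 background_grey = background_grey, grey_jitter = grey_jitter,
                 artifacts = art, seed = as.integer(seed)),
            class = "simulation_spec")
}

blank_canvas <- function(spec) {
  matrix(spec$background_grey, spec$image_size, spec$image_size)
}

# Stamp an anti-aliased stroke of the given width along the sampled centre
# line (xs, ys), with per-sample intensity, using max-composition.
stamp_curve <- function(canvas, xs, ys, width, intensity) {
  size <- nrow(canvas)
  rad <- width / 2
  R <- ceiling(rad + 1)
  for (ddx in -R:R) {
    for (ddy in -R:R) {
      if (sqrt(ddx^2 + ddy^2) > rad + 1.5) next
      ix <- as.integer(round(xs)) + ddx
      iy <- as.integer(round(ys)) + ddy
      dist <- sqrt((ix - xs)^2 + (iy - ys)^2)
      w <- pmin(1, pmax(0, rad + 0.5 - dist))
      inb <- ix >= 1L & ix <= size & iy >= 1L & iy <= size & w > 0
      if (!any(inb)) next
      val <- intensity[inb] * w[inb]
      cell <- cbind(ix[inb], iy[inb])
      cur <- canvas[cell]
      gt <- val > cur
      if (any(gt)) canvas[cell[gt, , drop = FALSE]] <- val[gt]
    }
  }
  canvas
}

curve_samples <- function(spec, phi_end = 2 * pi * spec$turns, step = 0.4) {
  b <- spec$params$b
  phi0 <- min(2 / b, phi_end / 10)
  s <- seq(0.5 * b * phi0^2, 0.5 * b * phi_end^2, by = step)
  list(s = s, phi = sqrt(2 * s / b), s_total = 0.5 * b * phi_end^2,
       phi_end = phi_end)
}

check_bounds <- function(spec, r_max) {
  margin <- max(spec$stroke_width_ref, spec$stroke_width_hand) / 2 + 1
  lim <- min(spec$params$origin[1] - 1, spec$params$origin[2] - 1,
             spec$image_size - spec$params$origin[1],
             spec$image_size - spec$params$origin[2])
  if (r_max + margin > lim) {
    stop("size error: spiral exceeds the image bounds", call. = FALSE)
  }
}

#' Render the reference spiral
#'
#' Rasterizes the ground-truth Archimedes spiral with the configured stroke
#' width and grey jitter on the light-grey background. Deterministic under
#' the spec's seed.
#'
#' @param spec A [simulation_spec()].
#' @return An [ink_image()].
#' @export
render_reference <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  cs <- curve_samples(spec)
  p <- spec$params
  theta <- cs$phi - p$theta_r
  r <- p$b * cs$phi
  check_bounds(spec, max(r))
  xs <- p$origin[1] + r * cos(theta)
  ys <- p$origin[2] + r * sin(theta)
  canvas <- with_local_seed(spec$seed, {
    intens <- 1 - spec$grey_jitter * stats::runif(length(xs))
    stamp_curve(blank_canvas(spec), xs, ys, spec$stroke_width_ref, intens)
  })
  ink_image(canvas, source_path = "synthetic:reference")
}

#' Render the tremulous hand drawing with its ground truth
#'
#' The hand curve is `r(theta) = b(theta + theta_r) + offset + d(s)` with a
#' radial sinusoidal tremor `d(s) = A sin(2 pi f (s / s_total) T + phase)`,
#' drawn at constant arc-length rate so that arc length is proportional to
#' time. Artifact flags inject blank arcs (gaps), small closed loops, short
#' excursions beyond half the ring spacing (crossings), and a near-origin
#' ink spike.
#'
#' @param spec A [simulation_spec()].
#' @return List with elements `image` (an [ink_image()] containing only the
#'   hand drawing) and `truth` (class `"ground_truth"`: the dense deviation
#'   record `d(s)`, tremor frequency/amplitude, drawing time, radial offset
#'   and the true [spiral_params()]).
#' @export
render_hand_drawing <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  # the hand curve sits hand_offset outside the reference, so it stops half a
  # turn early to stay inside the template (patients draw between the turns)
  cs <- curve_samples(spec, phi_end = 2 * pi * spec$turns - pi)
  p <- spec$params
  tt <- cs$s / cs$s_total * spec$t_to_draw
  d <- spec$tremor_amplitude *
    sin(2 * pi * spec$tremor_freq * tt + spec$phase)
  res <- with_local_seed(spec$seed + 1L, {
    dd <- d
    keep <- rep(TRUE, length(cs$s))
    if (spec$artifacts$crossings) {
      # short inward excursion past half the ring spacing: the drawn line
      # crosses the inner reference turn
      u <- stats::runif(1, 0.35, 0.8)
      dd <- dd - 1.2 * pi * p$b *
        exp(-((cs$s / cs$s_total - u) / 0.006)^2)
    }
    if (spec$artifacts$gaps) {
      for (g in seq_len(2L)) {
        u <- stats::runif(1, 0.15, 0.9)
        keep <- keep & abs(cs$s / cs$s_total - u) > 0.01
      }
    }
    r_h <- p$b * cs$phi + spec$hand_offset + dd
    theta <- cs$phi - p$theta_r
    xs <- p$origin[1] + r_h * cos(theta)
    ys <- p$origin[2] + r_h * sin(theta)
    check_bounds(spec, max(r_h))
    intens <- 1 - spec$grey_jitter * stats::runif(length(xs))
    canvas <- stamp_curve(matrix(0, spec$image_size, spec$image_size),
                          xs[keep], ys[keep], spec$stroke_width_hand,
                          intens[keep])
    if (spec$artifacts$loops) {
      for (l in seq_len(2L)) {
        i <- sample(which(cs$s / cs$s_total > 0.25 & cs$s / cs$s_total < 0.9), 1)
        rho <- stats::runif(1, 4, 8)
        psi <- seq(0, 2 * pi, length.out = 80)
        canvas <- stamp_curve(canvas,
                              xs[i] + rho * (1 - cos(psi)) * cos(theta[i]),
                              ys[i] + rho * (1 - cos(psi)) * sin(theta[i]) +
                                rho * sin(psi),
                              spec$stroke_width_hand,
                              rep(0.95, length(psi)))
      }
    }
    if (spec$artifacts$origin_spike) {
      ang <- stats::runif(1, 0, 2 * pi)
      canvas <- stamp_curve(canvas,
                            p$origin[1] + 4 * cos(ang) + c(0, 0.5, 1),
                            p$origin[2] + 4 * sin(ang) + c(0, 0.5, 1),
                            4, rep(1, 3))
    }
    canvas
  })
  truth <- structure(list(s = cs$s, d = d, s_total = cs$s_total,
                          phi_end = cs$phi_end,
                          tremor_freq = spec$tremor_freq,
                          tremor_amplitude = spec$tremor_amplitude,
                          t_to_draw = spec$t_to_draw,
                          hand_offset = spec$hand_offset,
                          params = p),
                     class = "ground_truth")
  list(image = ink_image(res, source_path = "synthetic:hand"), truth = truth)
}

#' Render a composite drawing (reference + hand + background)
#'
#' @param spec A [simulation_spec()].
#' @return List with elements `image` (composite [ink_image()]) and `truth`
#'   (see [render_hand_drawing()]).
#' @export
simulate_drawing <- function(spec) {
  ref <- render_reference(spec)
  hand <- render_hand_drawing(spec)
  img <- ink_image(pmax(ref$density, hand$image$density),
                   source_path = "synthetic:composite")
  list(image = img, truth = hand$truth, spec = spec)
}

#' Generate a cohort of synthetic drawings
#'
#' Draws `n` composite images with parameters sampled from realistic ranges
#' for mild-to-moderate tremor — amplitude A in \[3, 20\] px, frequency f in
#' \[3, 8\] Hz, rotation in \[0, 2 pi), stroke widths in \[1, 5\] px,
#' drawing time in \[8, 15\] s — and an assortment of artifacts (gaps,
#' loops, crossings, origin spikes) cycled across the cohort. Reproducible
#' per seed.
#'
#' @param n Cohort size (default 18).
#' @param seed RNG seed.
#' @param dir Optional output directory; when given, each sample is written
#'   as `S<k>.png` with a JSON ground-truth sidecar `S<k>_truth.json`, plus
#'   a `manifest.csv` of the sampled parameters.
#' @return List of `n` elements, each with `image`, `truth` and `spec`.
#' @export
make_cohort <- function(n = 18L, seed = 1L, dir = NULL) {
  stopifnot(n >= 1L)
  artifact_cycle <- list(
    list(), list(gaps = TRUE), list(loops = TRUE), list(crossings = TRUE),
    list(origin_spike = TRUE), list(gaps = TRUE, loops = TRUE))
  draws <- with_local_seed(seed, {
    lapply(seq_len(n), function(i) {
      list(A = stats::runif(1, 3, 20),
           f = stats::runif(1, 3, 8),
           theta_r = stats::runif(1, 0, 2 * pi),
           sw_ref = stats::runif(1, 1, 5),
           sw_hand = stats::runif(1, 1, 5),
           t_draw = stats::runif(1, 8, 15),
           phase = stats::runif(1, 0, 2 * pi),
           sub_seed = sample.int(2^30, 1),
           artifacts = artifact_cycle[[(i - 1L) %% length(artifact_cycle) + 1L]])
    })
  })
  cohort <- lapply(seq_len(n), function(i) {
    dr <- draws[[i]]
    spec <- simulation_spec(theta_r = dr$theta_r,
                            stroke_width_ref = dr$sw_ref,
                            stroke_width_hand = dr$sw_hand,
                            tremor_amplitude = dr$A, tremor_freq = dr$f,
                            t_to_draw = dr$t_draw, phase = dr$phase,
                            artifacts = dr$artifacts, seed = dr$sub_seed)
    simulate_drawing(spec)
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    man <- lapply(seq_len(n), function(i) {
      s <- cohort[[i]]$spec
      tr <- cohort[[i]]$truth
      id <- sprintf("S%d", i)
      write_image_png(cohort[[i]]$image, file.path(dir, paste0(id, ".png")))
      jsonlite::write_json(
        list(tremor_freq = tr$tremor_freq,
             tremor_amplitude = tr$tremor_amplitude,
             t_to_draw = tr$t_to_draw, hand_offset = tr$hand_offset,
             s_total = tr$s_total, phi_end = tr$phi_end,
             b = tr$params$b, theta_r = tr$params$theta_r,
             origin = tr$params$origin,
             artifacts = s$artifacts),
        file.path(dir, paste0(id, "_truth.json")),
        auto_unbox = TRUE, digits = NA)
      data.frame(sample = id, tremor_amplitude = s$tremor_amplitude,
                 tremor_freq = s$tremor_freq, theta_r = s$params$theta_r,
                 stroke_width_ref = s$stroke_width_ref,
                 stroke_width_hand = s$stroke_width_hand,
                 t_to_draw = s$t_to_draw,
                 artifacts = paste(names(Filter(isTRUE, s$artifacts)),
                                   collapse = "+"))
    })
    utils::write.csv(do.call(rbind, man), file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  cohort
}
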