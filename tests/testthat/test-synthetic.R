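test_that("the rendered reference stays inside the image and on the curve", {
  spec <- quick_spec(stroke_width_ref = 1, grey_jitter = 0,
                     background_grey = 0, theta_r = 2.2, seed = 8)
  img <- render_reference(spec)
  idx <- which(img$density >= 0.5, arr.ind = TRUE)
  expect_true(all(idx[, 1] >= 1 & idx[, 1] <= spec$image_size))
  # every ink pixel lies within 1 px (radially) of the analytic curve
  # (n = 0 covers the pre-origin arc -theta_r < theta < 0; pixels with
  # r < 15 px are skipped because a 1-px offset there is a large angle)
  p <- spec$params
  dx <- idx[, 1] - p$origin[1]
  dy <- idx[, 2] - p$origin[2]
  r <- sqrt(dx^2 + dy^2)
  thp <- atan2(dy, dx) %% (2 * pi)
  resid <- sapply(seq_along(r), function(i) {
    min(abs(r[i] - p$b * (thp[i] + 2 * pi * (-1):3 + p$theta_r)))
  })
  expect_lte(max(resid[r >= 15]), 1)

  # a spiral too large for the canvas is a size error
  expect_error(render_reference(simulation_spec(image_size = 100, b = 10)),
               "size error")
})

test_that("rendering is deterministic per seed and jitter varies across seeds", {
  a <- render_reference(quick_spec(seed = 9))
  b <- render_reference(quick_spec(seed = 9))
  c <- render_reference(quick_spec(seed = 10))
  expect_identical(a$density, b$density)
  expect_false(identical(a$density, c$density))
})

test_that("a zero-tremor hand drawing follows the reference at its offset", {
  spec <- quick_spec(tremor_amplitude = 0, grey_jitter = 0, seed = 14)
  hand <- render_hand_drawing(spec)
  idx <- which(hand$image$density >= 0.5, arr.ind = TRUE)
  p <- spec$params
  r <- sqrt((idx[, 1] - p$origin[1])^2 + (idx[, 2] - p$origin[2])^2)
  thp <- atan2(idx[, 2] - p$origin[2], idx[, 1] - p$origin[1]) %% (2 * pi)
  resid <- sapply(seq_along(r), function(i) {
    min(abs(r[i] - (p$b * (thp[i] + 2 * pi * (-1):3 + p$theta_r) +
                      spec$hand_offset)))
  })
  expect_lte(max(resid), spec$stroke_width_hand / 2 + 1)
})

test_that("the tremor record crosses zero 2 f T times", {
  spec <- quick_spec(tremor_amplitude = 10, tremor_freq = 5, t_to_draw = 10,
                     seed = 15)
  truth <- render_hand_drawing(spec)$truth
  crossings <- sum(diff(sign(truth$d)) != 0)
  expect_equal(crossings, 2 * 5 * 10, tolerance = 0.02)
})

test_that("the ground-truth sinusoid has RMS A / sqrt(2) within 1%", {
  truth <- render_hand_drawing(quick_spec(tremor_amplitude = 14, seed = 16))$truth
  expect_equal(sqrt(mean(truth$d^2)), 14 / sqrt(2), tolerance = 0.01)
})

test_that("the gaps artifact leaves blank arcs (missing profile columns)", {
  spec <- quick_spec(artifacts = list(gaps = TRUE), seed = 17)
  hand <- render_hand_drawing(spec)
  fimg <- flatten_image(hand$image, spec$params)
  fimg <- crop_rect(fimg, y_range = spec$hand_offset +
                      c(-0.7, 0.7) * pi * spec$params$b)
  prof <- extract_profile(fimg)
  miss <- rle(is.na(prof$y))
  expect_gte(max(miss$lengths[miss$values]), 0.005 * length(prof$y))
})

test_that("a cohort is reproducible, in range, and fully sidecar'd on disk", {
  dir <- withr::local_tempdir()
  cohort <- make_cohort(n = 6, seed = 99, dir = dir)
  again <- make_cohort(n = 6, seed = 99)
  expect_identical(cohort[[3]]$image$density, again[[3]]$image$density)
  expect_identical(cohort[[5]]$truth$d, again[[5]]$truth$d)

  for (s in cohort) {
    expect_gte(s$spec$tremor_amplitude, 3)
    expect_lte(s$spec$tremor_amplitude, 20)
    expect_gte(s$spec$tremor_freq, 3)
    expect_lte(s$spec$tremor_freq, 8)
    expect_gte(s$spec$params$theta_r, 0)
    expect_lt(s$spec$params$theta_r, 2 * pi)
    expect_gte(min(s$spec$stroke_width_ref, s$spec$stroke_width_hand), 1)
    expect_lte(max(s$spec$stroke_width_ref, s$spec$stroke_width_hand), 5)
  }

  expect_length(list.files(dir, pattern = "^S\\d+\\.png$"), 6L)
  expect_length(list.files(dir, pattern = "_truth\\.json$"), 6L)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 6L)
  truth3 <- jsonlite::read_json(file.path(dir, "S3_truth.json"),
                                simplifyVector = TRUE)
  expect_equal(truth3$tremor_freq, cohort[[3]]$truth$tremor_freq)
})

test_that("fit from clicks on the rendered curve recovers b and theta_r", {
  # whole-pixel clicks: angular precision scales with radius, so this uses a
  # scan-resolution template (1200 px) and points one and three turns out
  for (seed in 1:5) {
    set.seed(seed)
    spec <- simulation_spec(image_size = 1400L, turns = 5,
                            theta_r = runif(1, 0, 2 * pi), seed = seed)
    img <- render_reference(spec)
    p <- spec$params
    click <- function(theta) {
      xy <- round(p$origin + spiral_xy(p, theta)[1, ])
      expect_gte(img$density[xy[1], xy[2]], 0.5)  # the click is on ink
      polar_from_cartesian(xy, p$origin)
    }
    fit <- fit_from_two_points(click(1.5 * pi), click(7.5 * pi),
                               zones = c(1, 4))
    expect_equal(fit$b, p$b, tolerance = 0.02)
    expect_lte(abs(fit$theta_r - p$theta_r), 0.05)
  }
})
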