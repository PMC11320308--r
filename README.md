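# spiraltrace

Tremor quantification from hand-drawn Archimedes spirals.

The spiral test is a standard clinical assessment for essential tremor and
Parkinson's disease: the patient draws a spiral inside the space of a
printed Archimedes spiral, and the drawing is graded for tremor. Most of
this data exists as scanned or photocopied paper — rotated and translated
arbitrarily on the page, with multi-pixel strokes of varying grey value,
light-grey backgrounds, and occasional gaps, loops and crossings.
`spiraltrace` turns such an image into a one-dimensional discrete signal
and a compact spectral feature set:

1. **Fit** the reference spiral r = b(θ + θ_r) in closed form from two
   user-supplied points: θ_r = (r₂θ₁ − r₁θ₂)/(r₁ − r₂),
   b = (r₁ − r₂)/(θ₁ − θ₂), after unwrapping each angle by its turn (zone)
   index.
2. **Flatten** every ink pixel through the zone-family map
   (x, y) = (θ + θ_r, r − b(θ + θ_r)), applied once per candidate turn
   index, so spiral segments self-stitch into horizontal bands spaced 2πb
   apart and the hand drawing into a family of parallel curves.
3. **Extract** a single-valued profile (first sufficiently dark pixel per
   column, scanning upward), convert the abscissa to arc length
   s = ½bφ², crop the near-origin noise, resample to N = 1000 uniform
   samples, and normalize to zero mean and a ±1000 px bound, keeping the
   pre-normalization RMS as the tremor amplitude in pixels.
4. **Reduce**: real FFT (N_coeff = N/2 + 1 = 501 coefficients), brick-wall
   low-pass at 0.4·N_coeff, truncation to N_trunc = 150 magnitude/phase
   pairs, inverse FFT, and the percent RMS truncation error. With the
   drawing time T recorded, coefficient k maps to
   f_k = k/(T · cropping_ratio) Hz and the tremor peak is located in the
   1–12 Hz band.

A synthetic-image generator renders tremulous drawings with known ground
truth (rotation, stroke width, grey jitter, gaps, loops, crossings, origin
spikes) for validation; no clinical data ships with the package.

## Worked example

Simulate a drawing with a 10 px, 5 Hz tremor drawn in 10 s, then run the
full pipeline:

```r
library(spiraltrace)

spec <- simulation_spec(tremor_amplitude = 10, tremor_freq = 5,
                        t_to_draw = 10, theta_r = 0.8, seed = 7)
sim <- simulate_drawing(spec)

# two on-spiral points (from config in real use), zones 1 and 2
origin <- c(300.5, 300.5)
params <- fit_from_two_points(
  polar_from_cartesian(c(258.2, 300.5), origin),
  polar_from_cartesian(c(190.7, 300.5), origin),
  zones = c(1, 2), origin = origin)
params
#> Archimedes spiral: r = 10.743 * (theta + 0.79587)
#>   origin: (300.50, 300.50) px (y-up)

fimg <- flatten_image(sim$image, params)
band <- crop_rect(fimg, y_range = pi * params$b * c(0.3, 1.7))
prof <- crop_noise_region(to_arc_length(extract_profile(band)), s_min = 50)
sig  <- resample_and_normalize(prof, N = 1000)
sig$t_to_draw <- 10
sig
#> discrete signal: N = 1000 samples, s in [50.1, 2597.4] px
#>   cropping_ratio = 0.9807, rms_raw = 7.056 px, t_to_draw = 10.0 s

run_metrics(sig)
#> tremor peak: 5.00 Hz (k = 49) in band [1, 12] Hz
#> amplitude (RMS): 7.06 px; truncation to 150 coefficients: 5.25% RMS error
```

The fitted scale and rotation match the generating spiral (b = 10.743,
θ_r = 0.8); the recovered peak is the generated 5 Hz; the RMS amplitude
7.06 px is the expected A/√2 = 7.07 px for a 10 px sinusoidal tremor; and
truncating 501 coefficients to 150 reconstructs the signal with a 5.25%
RMS error.

The same steps are scriptable from a shell via `inst/cli/spiraltrace`
(subcommands `extract`, `spectrum`, `metrics`, `simulate`, configured by a
JSON file in place of interactive clicks).

## Layout

- `R/` — spiral geometry, image I/O, flattening, signal extraction,
  spectral reduction, tremor metrics, synthetic generator, pipeline drivers
- `inst/cli/spiraltrace` — command-line front-end
- `vignettes/spiral-tremor-quantification.Rmd` — methods and design notes
- `tests/testthat/` — unit, property and acceptance tests (all fixtures
  generated in code)
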