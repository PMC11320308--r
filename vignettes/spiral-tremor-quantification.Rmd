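---
title: "Quantifying tremor from hand-drawn Archimedes spirals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tremor from hand-drawn Archimedes spirals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(spiraltrace)
```

## The problem

The Archimedes spiral test is a standard bedside assessment for movement
disorders such as essential tremor and Parkinson's disease: the patient
draws a spiral inside the space of a printed reference spiral, and a
clinician grades the tremor from the drawing. Most clinics still work with
pencil and paper, so the drawings reach analysis as photocopied or scanned
raster images — rotated and translated by unpredictable amounts, with
strokes several pixels wide, variable grey values, light-grey scan
background, and occasionally gaps, closed loops, or lines crossing the
reference curve.

`spiraltrace` converts such an image into a one-dimensional discrete signal
(radial deviation of the hand drawing versus arc length along the spiral)
and compresses that signal into a small set of FFT coefficients with a
quantified truncation error, a tremor-frequency estimate in Hz, and an RMS
tremor amplitude in pixels.

## Model and procedure

### Spiral fit

The reference template is the Archimedes spiral

$$ r = b\,(\theta + \theta_r), \qquad b > 0, $$

where $b$ (pixels per radian) sets the scale and $\theta_r$ the rotation of
the template on the page. Both are recovered in closed form from the polar
coordinates of two user-supplied points on the curve:

$$ \theta_r = \frac{r_2\theta_1 - r_1\theta_2}{r_1 - r_2}, \qquad
   b = \frac{r_1 - r_2}{\theta_1 - \theta_2}. $$

The measured polar angle of a pixel is only known modulo $2\pi$; each point
is therefore unwrapped by a *zone* (turn) index before the fit,
$\theta = \theta' + 2\pi(k-1)$ with $\theta' \in [0, 2\pi)$. Zone one is the
innermost turn and carries no offset. The convention that the turn counter
starts at zero offset (rather than one full turn) is the one that makes a
point on the first turn keep its measured angle; the offset is configurable
(`zone_offset`) for workflows that count turns differently. All angles are
mathematical (counter-clockwise, y-up); the image's row order is flipped
once at the I/O boundary so the geometry never sees y-down coordinates.

### Flattening by the zone-family map

The transform

$$ x = \alpha\,(\theta + \theta_r), \qquad
   y = \beta\,\bigl(r - b\,(\theta + \theta_r)\bigr) $$

maps the fitted spiral onto the horizontal axis ($y = 0$). For an arbitrary
ink pixel, however, the turn index $n$ needed to unwrap $\theta$ is unknown
and cannot be assigned robustly by image processing. The package therefore
maps *every* ink pixel once per candidate index $n$ in a configurable list
(default $n = 1,2,3,4$), producing a family of points spaced exactly
$(2\pi\alpha,\; -2\pi b\beta)$ apart. Segments of the reference spiral then
self-stitch into horizontal bands with vertical spacing $2\pi b$, and the
hand drawing self-stitches into a family of parallel curves; the user's only
intervention is a crop rectangle (supplied via config, not clicks) that
isolates one stitched copy of the drawing. Patients draw between the turns
of the template, so the drawing's band sits roughly half the ring spacing
($\pi b$) away from the reference band and the two never overlap in the
crop.

The transform defines no target raster, so rasterization is an engineering
choice: mapped points deposit into the nearest grid cell and each cell keeps
the *maximum* deposited density, preserving darkest-ink semantics for the
extraction step. The default column pitch is one source pixel of arc at the
mean ring radius ($1/\bar{r}$ radians) and the row pitch is one source
pixel; pixels below a density floor (default 0.1) are skipped as background.

### Profile extraction

For each flattened column the rows are scanned in increasing $y$ and the
first cell at or above a density threshold (default 0.5) gives the column's
value. On a closed loop this deliberately latches onto the *lower* branch —
the single-valued reading the method prescribes; it slightly underestimates
amplitude on heavily looped drawings but does not disturb the frequency
peak. Columns where no cell reaches the threshold fall back to the column's
density maximum; empty columns are recorded as missing and filled by linear
interpolation at resampling time (a warning is raised when a bridged gap
exceeds 5% of the extent). Two descriptions coexist for this step —
"darkest pixel of the column" and "first sufficiently strong pixel upward" —
and only the first-hit rule reproduces the documented lower-branch behaviour
on loops, so first-hit is primary and the darkest-pixel rule is the
fallback.

### Arc length, cropping ratio, resampling, normalization

Integrating $ds = r\,d\theta$ along the spiral gives
$s = \tfrac{1}{2} b \varphi^2$ with $\varphi = \theta + \theta_r$, which
converts the flattened abscissa into arc length in pixels. The first few
millimetres near the centre are noisy (a one-pixel offset there subtends a
large angle, and pixels drawn before the angular origin are mis-unwrapped by
one turn), so a configurable `s_min` crop removes the near-origin region.

The **cropping ratio** tracks how much of the drawn record survives the
crops, because it rescales the frequency axis. The tool defines it as the
retained fraction of arc-length extent, with the record anchored at the
$x = 0$ edge: the initial value is $(s_\max - s_\min)/s_\max$ for the
extracted profile, and each subsequent crop multiplies by
retained-extent/previous-extent. The flattened image's own x-extent is *not*
used as the baseline, because it includes family members beyond the
drawing's end and would understate the ratio. `crop_rect` records its
retained x-range; the warning it emits when the $x = 0$ edge is excluded
exists precisely because that edge anchors the accounting.

The profile is interpolated onto $N = 1000$ uniform arc-length samples
(even $N$ keeps the real-DFT bookkeeping simple; the resulting Nyquist index
of 500 sits far above the $\le 12$ Hz tremor band for realistic drawing
times), the mean is removed, the pre-normalization RMS is recorded in
pixels, and the signal is scaled so its absolute value peaks at exactly
1000. "Bounded by 1000 pixels" is read as scaled-to-bound, which makes
signals comparable across drawings; the amplitude information removed by
normalization survives in the recorded RMS.

### Spectrum, truncation, error

The real DFT of an $N$-sample signal has $N_{\mathrm{coeff}} = N/2 + 1$
magnitude/phase pairs (501 for $N = 1000$). Analysis applies, in order:

1. a brick-wall low-pass at index $\lfloor 0.4\,N_{\mathrm{coeff}} \rfloor$
   (200 for $N = 1000$) to remove high-frequency noise — the cutoff shape is
   a design choice, as only the cutoff fraction is prescribed;
2. truncation to the leading $N_{\mathrm{trunc}} = 150$ pairs, a
   $2 \times 150 = 300$-parameter representation;
3. inverse FFT of the truncated spectrum and the percent RMS error
   $100\,\mathrm{RMS}(y - \hat y)/\mathrm{RMS}(y)$ against the untruncated
   signal.

The error denominator is the signal RMS: the printed percentages never state
their denominator, and signal RMS is the convention that makes the figure
invariant under the fixed $\pm 1000$ normalization (the alternative,
normalizing by the 1000-px bound, is computable from the same report).
Phases of zeroed coefficients are set to 0 for determinism. A
Savitzky–Golay filter (window 51, order 3) is available for *display only*;
`savgol_display` returns a smoothed copy and never touches the analysed
data. The truncated feature vector — 150 magnitudes, 150 phases, plus the
one pre-normalization RMS — is the compact representation intended for
downstream statistical models.

### Frequency axis and tremor metrics

A drawing carries no time base, so Hz labelling requires the wall-clock
drawing time $T$. Under the constant drawing-speed assumption (arc length
proportional to time), the retained record spans $T \cdot
\mathrm{cropping\_ratio}$ seconds and coefficient $k$ maps to

$$ f_k = \frac{k}{T \cdot \mathrm{cropping\_ratio}} \ \mathrm{Hz}, $$

the standard DFT bin width for that effective duration. The tremor peak is
the magnitude argmax within a band of interest, default 1–12 Hz: the 12 Hz
ceiling is the upper end of clinically relevant tremor, and the 1 Hz floor
keeps the drawing's slow drift (which dominates the lowest coefficients)
out of the search. Ties resolve to the lower frequency. Without a recorded
drawing time the peak is reported in coefficient units with a warning.

## The synthetic generator

Real validation drawings cannot ship with the package, and no generative
model of volunteer drawings is prescribed, so the generator implements the
simplest model consistent with the time–frequency reasoning above: the hand
curve is the reference spiral plus a radial offset and a radial sinusoid
drawn at constant arc-length rate,

$$ r(\theta) = b(\theta + \theta_r) + \mathrm{offset} +
   A \sin\!\bigl(2\pi f\,(s/s_{\mathrm{total}})\,T + \phi\bigr). $$

The offset defaults to half the ring spacing ($\pi b$), where patients are
asked to draw; the hand record stops half a turn before the template's edge
so it stays inside the page. Strokes are stamped as anti-aliased disks with
per-sample grey jitter emulating pen pressure and scan grey levels, on a
light-grey background. Artifact flags inject blank arcs (gaps), small
closed loops, a short inward excursion past half the ring spacing that
crosses the inner reference turn (crossings), and a near-origin ink spike.

Cohort defaults are chosen once as realistic for mild-to-moderate tremor:
amplitude $A \in [3, 20]$ px, frequency $f \in [3, 8]$ Hz, rotation
$\theta_r \in [0, 2\pi)$, stroke widths $\in [1, 5]$ px, drawing time
$\in [8, 15]$ s, with the artifact assortment cycled across 18 samples.
Every sample carries its ground truth ($b$, $\theta_r$, $d(s)$, $f$, $A$,
$T$), so fitting, flattening, extraction, amplitude, and frequency can all
be validated without external data.

What the generator does *not* emulate: biomechanical tremor structure
(harmonics, amplitude drift, direction-dependent tremor), pen-lift
curvature, paper texture, or the specific distorted templates some clinics
use. Passing tests on this cohort therefore demonstrate the geometry,
extraction and spectral machinery under controlled artifacts — not clinical
performance on real scans.

```{r cohort, eval = FALSE}
cohort <- make_cohort(n = 18, seed = 42)
tab <- evaluate_cohort(cohort = cohort)
summary(tab$rms_error_pct)
```

## Numerical choices and degenerate inputs

* **Two-point fit**: coincident radii or unwrapped angles raise a
  degenerate-fit error; a fitted $b \le 0$ (points selected in the wrong
  order or zones) raises an invalid-selection error. With whole-pixel
  coordinates the angular precision of a point scales as $1/r$, so
  parameter recovery to $0.05$ rad in rotation needs either
  scan-resolution images (the recovery test uses a 1400-px template) or
  config-supplied sub-pixel coordinates, which is how the pipeline is
  normally driven.
* **Flattening**: only the half-plane $x \ge 0$ is kept. The sliver drawn
  before the angular origin ($-\theta_r < \theta < 0$) is unwrapped one
  turn too high by the default $n$-list; it lands outside the crop band and
  inside the near-origin noise region, which `s_min` removes.
* **Extraction**: an all-empty band raises a no-signal error; a constant
  deviation profile cannot be normalized and raises a degenerate-signal
  error.
* **Resampling**: interpolation is linear; missing end columns extend the
  nearest value.
* **FFT**: odd $N$ is rejected (the resampler always emits even $N$);
  reconstruction rebuilds the Hermitian spectrum, so the inverse transform
  of an untruncated spectrum reproduces the signal to machine precision.
* **Problem sizes**: the test-suite and validation harness render 480–700
  px images with 3–4 turns and a 1000-sample signal — compact enough that
  the full 18-drawing cohort evaluates in seconds, while keeping roughly
  one flattened column per source pixel of arc.

## Known limitations

* Loops are read single-valued on the lower branch; heavy looping biases
  the amplitude low (the frequency peak is unaffected).
* Multi-branch tracking, sub-pixel centerline estimation, least-squares or
  robust multi-point spiral fitting, and automatic crop selection are out
  of scope by design.
* Severely distorted templates flatten to wavy, overlapping bands; the tool
  accepts an externally cleaned flattened image or mask rather than
  offering in-tool pixel editing.
* The Hz axis inherits the constant-drawing-speed assumption; speed
  variations smear the tremor peak.
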