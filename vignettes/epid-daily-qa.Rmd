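---
title: "EPID-based daily linac QA: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EPID-based daily linac QA: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidqa)
```

## The measurement problem

Daily quality assurance of a medical linear accelerator checks, before the
first patient, that dose output, beam quality, beam shape and field geometry
have not drifted overnight. Conventional daily-QA phantoms take 5–10 minutes
of setup per machine; an electronic portal imaging device (EPID) is already
mounted on the gantry, digital, and has sub-millimetre resolution, so the
same checks can run from two quick portal images.

`epidqa` implements that workflow. The daily session is two acquisitions of a
10 cm × 10 cm field at 100 MU with the gantry at 0°: one open field
(image *I1*) and one with the 60° wedge (*I2*). From them the package
computes:

* **Output constancy** — the mean signal µ of a 10 mm × 10 mm region of
  interest at the detected field centre of *I1* (exactly 40 × 40 pixels on a
  0.25 mm isocenter grid). Day-to-day constancy of µ tracks dose-per-MU.
* **Beam quality (BQ)** — the wedge factor `W = µ_wedge / µ_open`. The wedge
  preferentially attenuates low-energy photons, so W moves when beam energy
  moves; no water tank is needed. The classical depth-dose ratio
  `BQ = D20/D10` is provided as a bookkeeping utility
  (`depth_dose_bq()`) for cross-checks against chamber measurements.
* **Flatness** — `F = (Dmax − Dmin)/Dcenter × 100 %` over the central 80 %
  of each profile.
* **Symmetry** — `S = max |D(p) − D(2c − p)| / Dcenter × 100 %`, the largest
  imbalance of points mirrored about the field central axis `c`.
* **Field size and centre** — from sub-pixel field edges (below).

All of these are compared daily against a stored benchmark acquired with the
machine in a known-good state (`create_baseline()` / `evaluate_daily()`).
Because every dose-like quantity is evaluated as a ratio or difference to
that benchmark, the arbitrary 16-bit scaling some imagers apply on export
cancels and plays no role.

## Edge detection and field geometry

A field edge is the inflection point of the penumbra: the position where the
profile's first derivative is extremal and its second derivative crosses
zero. For discrete, possibly noisy samples the package:

1. averages a band of 10 adjacent lines (about 2.5 mm at 0.25 mm/px) into
   each profile — wide enough to suppress single-pixel noise, narrow enough
   not to blur a slightly rotated edge;
2. smooths with a Gaussian of σ = 1 sample;
3. differentiates by central differences;
4. takes the maximum (rising edge) and minimum (falling edge) of the
   derivative and refines each with a three-point parabola, giving sub-pixel
   edge positions.

For a smooth penumbra the derivative extremum *is* the second-derivative
zero, so step 4 is the discrete version of the analytic definition. If two
derivative samples tie exactly (an edge falling midway between two pixel
centres does this on noiseless data), the candidate nearest the profile
midline is taken and the parabola lands on the midpoint anyway; the event is
logged.

Field geometry runs this twice: pass 1 through the grid centre yields a
provisional centre from edge midpoints, pass 2 re-extracts the profiles
through that centre. For a rectangular field the midpoint-of-edges centre
coincides with the intersection of the field diagonals. A centre that moves
more than 2 px between passes indicates a badly decentred or non-rectangular
field and triggers a warning rather than silent acceptance.

Coordinates are fixed package-wide: 0-based pixel indices, a pixel's position
is its centre, origin at the grid centre, X = crossline increasing with
column index, Y = inline with the gantry side positive, and every position or
size reported in mm at the isocenter plane (detector mm × SAD/SDD).

`Dcenter` in the flatness/symmetry denominators is the profile value linearly
interpolated at the detected field centre — not the profile maximum — which
keeps both definitions meaningful for centrally peaked
flattening-filter-free (FFF) beams. Flatness itself is not reported for FFF
beams (there is no flat region to grade); symmetry, size, centre, output and
W are computed identically.

## Tolerances

`tolerance_set()` defaults: output ±2.5 %, wedge-factor BQ ±2 %,
flatness/symmetry ±2 percentage points absolute, size and centre ±2 mm. The
output tolerance is deliberately tighter than the generic 3 % daily figure:
a flat panel's repeatability floor (≈0.1 %) is an order of magnitude above a
farmer chamber's, so some headroom of the tolerance is already consumed by
the instrument. All values are clinic-overridable in the run config; a
parameter fails when |deviation| strictly exceeds its tolerance. Baselines
expire after 365 days; evaluations against an expired baseline are computed
but flagged `stale_baseline`.

The BQ comparison uses the *ratio* `W/W_baseline` (as percent-from-100)
rather than the difference — consistent with output, and invariant to any
common gain. Whether to use ratio or difference was genuinely open; ratio
was chosen and is documented here.

## The synthetic beam model

Real portal images cannot ship with a package, so all validation runs on a
generative model (`beam_spec()` / `generate_portal_image()`) whose ground
truth is known by construction:

```
signal(x, y) = offset + MU · gain · Px(x) · Py(y) · M(x, y) · T(x) + ε
```

* `Px`, `Py` are smoothed top-hats with logistic (sigmoid) edges at
  `shift ± field/2`. `penumbra_sigma` (default 2 mm) is the
  Gaussian-equivalent standard deviation of the edge spread; the logistic
  scale is `penumbra_sigma·√3/π` (variance-matched). This keeps the sigmoid's
  analytic simplicity while making "2 mm penumbra" mean what a physicist
  expects: the central 80 % of a 10 cm field stays flat to better than
  0.1 %.
* `M` models the filter: 1 for an ideal flattened beam, a separable
  quadratic horn boost (amplitude `horn_amplitude` at the nominal edge) for
  horned beams, and the radial cone `max(0, 1 − fff_falloff·r)` for FFF
  beams. The default FFF falloff of 0.004/mm gives a visibly peaked profile
  whose ROI-shift response grows sharply beyond ~10 mm offsets; it is a
  knob, not a claim about any particular linac.
* `T` is the wedge: `transmission · exp(−gradient·(x − shift_x))`. The bulk
  `transmission` (default 0.55) reproduces a realistic 60°-wedge factor near
  0.5–0.6; the `gradient` (default 0.012/mm) provides the transverse tilt. A
  pure normalized exponential would force W ≈ 1 and make the BQ surrogate
  vacuous, which is why the bulk factor exists.
* `ε` is i.i.d. Gaussian with standard deviation `noise_frac × local
  signal`, drawn from the spec's `seed` without disturbing the caller's RNG
  state; images are bit-identical for a fixed seed.

Defaults emulate an iViewGT-class acquisition: 1024 × 1024 panel, 0.4 mm
detector pitch at SDD 1600 mm and SAD 1000 mm (0.25 mm/px at isocenter,
40 cm × 40 cm field of view), 100 MU, gain 100 signal/MU (plateau ≈ 10⁴,
comfortably inside 16 bits up to 600 MU).

**What the model does not emulate:** ghosting and saturation of the panel,
off-axis energy response, scatter and glare, beam spectral changes, detector
ageing, or mechanical sag. Passing tests therefore demonstrate the
correctness of the *analysis* — edge localization, metric definitions,
threshold logic — under controlled image formation, not the clinical
behaviour of any EPID. The repeated-replicate tests use a 512 × 512 panel at
the same 0.25 mm isocenter pixel so their runtime stays in seconds; results
are pixel-pitch-driven, not field-of-view-driven.

## Validation experiments

Four commissioning-style experiments are packaged (`cmd_experiment()`), each
on synthetic series:

* **Linearity** — µ versus MU over the 27-exposure ladder (1–10, 20, 40, 80,
  95–105, 150, 200, 300 MU) or the 8-exposure ladder (10–600 MU), OLS fit
  with `R² = 1 − SS_res/SS_tot`. Noiseless ladders fit to R² = 1 at machine
  precision and recover the generator slope to 3 significant figures; with
  1 % per-pixel noise the 1600-pixel ROI averages it down and mean R² stays
  above 0.998.
* **Shift sensitivity** — output and BQ deviation `(shifted − ref)/ref ×
  100 %` for ROI displacements of 1–10, 15, 20 and 30 mm in the four
  cardinal directions, both ROIs displaced identically (an EPID setup error
  moves both acquisitions the same way). The sign convention makes downhill
  shifts negative, as observed on peaked beams.
* **Adjacent field-size steps** — square fields from 94 to 106 mm in 2 mm
  steps; the mean of the six adjacent measured-size differences per axis
  must recover 2.00 mm within one pixel (0.25 mm).
* **Collimator-pair centre** — images at collimator 90° and 270° carry
  equal-and-opposite collimator asymmetry; the component-wise mean of their
  detected centres recovers the true radiation centre within half a pixel.

## Numerical choices and degenerate inputs

* Sub-pixel refinement clamps the parabola vertex to ±1 sample, so a noisy
  derivative cannot throw an edge outside its bracket.
* Profiles need ≥16 samples, uniform spacing to 1 nm, finite non-negative
  values; monotone ramps (no opposite-sign derivative extrema) and extrema
  sitting on the profile boundary raise detection errors naming the side.
* The central ROI uses pixels whose centres fall inside the square
  (half-open comparisons with a 1 nm guard), which yields exactly 40 × 40
  pixels at 0.25 mm/px; an ROI that leaves the panel is a geometry error —
  flagged but non-fatal inside the sensitivity scan.
* TIFF files carry no geometry, so the reader refuses to guess: detector
  pitch and SDD must come from the machine profile. Polarity-inverted
  exports (beam darker than background) are detected by comparing a central
  40 × 40-px patch to a 10-px border frame and flipped as `max − value`,
  with a log message.
* 16-bit quantization on TIFF write is documented and exact for integer
  signals; the DICOM writer stores unsigned 16-bit with the inverse rescale
  applied. The DICOM reader handles Explicit VR Little Endian only — the
  transfer syntax portal-dose exports actually use.
* The wedge image's ROI is evaluated at the *open* field's detected centre:
  both images come from the same session, and the wedge gradient makes its
  own centre estimate slightly less robust along X. The open/wedge field
  sizes must agree within 5 mm or the pair is rejected as a mixed-up
  acquisition.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run entirely on synthetic
images: the 1024² study-condition panel for single-image checks and the
seven-field size series; a 512² panel (same pixel pitch) for the 200-replicate
noise-robustness sweep and the multi-image ladders in unit tests; 4 × 27
noisy 1024² images for the linearity figure of merit. The full suite
completes in well under a minute on one core.

## Limitations

* The wedge-factor surrogate detects energy *change*; it does not measure
  beam quality absolutely, and its sensitivity depends on the wedge angle.
* Detector calibration (dark/flood field, gain, bad-pixel maps) is assumed
  done by the vendor software; the package analyzes calibrated exports.
* Electron beams are not covered; the same machinery would apply with a
  suitable attenuator in place of the wedge.
* Absolute field sizes from derivative-based edges can sit a few tenths of a
  millimetre from light-field-calibrated values on real machines; daily QA
  tracks the *trend* against the benchmark, which is unaffected.
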