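---
title: "Methods: marker-less MRI-based displacement quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker-less MRI-based displacement quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrikin)
```

## The measurement problem

Fluoroscopy-based skeletal motion measurement (RSA, scientific rotoscoping,
XROMM) registers 3-D bone models to their silhouettes in calibrated x-ray
views. `mrikin` implements the MRI analogue: rigid solids are imaged as
single-plane or biplanar MR slices, 3-D models of the solids are registered
to their image silhouettes ("rotoscoping"), and relative displacements are
read off in a joint coordinate system. MR slices are tomographic — a slab of
tissue is integrated, not projected — so both the calibration model and the
rendering operator differ from the x-ray case, and those differences drive
most of the design choices below.

Because the original bench experiment's raw data (scanner images, human
rater measurements) are not available, every stage is exercised against a
synthetic phantom whose ground truth is known. The phantom generator is not
a test fixture but part of the package's contract: its defaults *are* the
study conditions.

## Phantom and imaging model

**Solids.** Two cubes of side 40 mm with an hourglass bore along the body
y-axis: a symmetric double frustum tapering from 7 mm diameter at the faces
to 3 mm at the centre. The base diameter matches the physical phantom; the
waist diameter is unreported for the original object, so 3 mm is a default
exposed as `bore_waist_diameter`. Solids are implicit: a signed-distance
field (Chebyshev box distance carved by the bore's taper radius) classifies
material exactly, and a soft ramp one pixel wide converts distance to
occupancy so silhouettes respond smoothly to sub-pixel pose changes. The
cubes sit stacked along y (the coil-bore axis, like vertebral bodies) with
centres 50 mm apart, leaving a 10 mm gap that is preserved during z/x
translations; rotation trials rotate the moving cube about its own centre,
which is therefore 50 mm from the stationary cube's centre.

**Calibration grid.** Four 80 mm × 80 mm plates stacked 30 mm apart along y,
each with a centred 4×4 array of 2 mm beads at 20 mm pitch. A 4×4 lattice is
4-fold symmetric, so three extra axis beads on the first two plates (8 mm
and 6 mm off the corner bead, along −x and −z) break the symmetry; the
distinct offsets let the correspondence step tell the x from the z marker.
The plate side follows from the lattice plus margin (a printed plate "area"
of 80 mm² is geometrically impossible for a 60 mm lattice; the plates are
modelled 80 mm square).

**Imaging.** Each pixel of a slice holds the fraction of its slab column
(pixel footprint × slab thickness) occupied by material — saline-soaked
solid bright, bore/air dark — evaluated at 5 integration points across the
slab, then blurred in-plane (Gaussian, FWHM 1 mm by default) and given
additive Gaussian noise (SD 3% of full signal by default). No
pulse-sequence contrast physics is modelled: the technique uses silhouette
morphology only, so the two scanner protocols are represented purely by
their geometry — "T1-like" 0.78125 mm pixels (200 mm field of view over a
256 matrix) with a 5 mm slab, "fast-like" 0.98 mm pixels with an 8 mm slab,
and a T2-like 3 mm slab for the grid scans. What the simulator deliberately
omits: coil-sensitivity shading, susceptibility and motion artifacts,
geometric gradient distortion, and any human-rater behaviour. Passing tests
therefore demonstrate correctness of the algorithmic chain under its own
imaging model, not scanner-grade accuracy claims.

Because the pixel value is an occupancy *fraction*, widening the slab can
lower values where the slab extends past the solid along its normal; the
monotonicity property (wider slab never darkens a pixel) holds in the regime
the study operates in — slabs inside the solids' extent — and is tested
there.

**Trial designs.** Translations 0–20 mm in 5 mm steps, 7 replicates per
level (35 frames); rotations 0–20° in 5° steps, 6 per level (30 frames);
biplanar z+x translations, 4 per level (20 frames) with two orthogonal
views per frame. Frame 0 is the neutral position. Every non-neutral frame
adds a uniform ±0.2 mm/±0.2° placement jitter: the physical placements were
caliper-verified (0.02 mm sensitivity) but hand-positioned, and 0.2 mm —
about a quarter voxel — is a realistic bound for manual bench positioning;
it is configurable.

## Calibration

Each plate's control points are coplanar, which makes the classical
11-parameter 3-D DLT degenerate. The well-posed equivalent is an
8-parameter plane-to-image homography per plate, fit by Hartley-normalized
least squares (the stored normalized coefficient vector has unit Frobenius
norm, hence every stored coefficient magnitude ≤ 1), with the known 30 mm
plate spacing supplying the out-of-plane scale. Since MR slices are
tomographic, the assembled volume model is affine-orthographic — a single
2×2 in-plane matrix plus offset shared by all plates — rather than a
perspective camera.

Bead digitization is automated: light smoothing (1 px Gaussian), Otsu
threshold floored at a quarter of the smoothed peak (the floor guards
against Otsu splitting the background noise when foreground pixels are a
fraction of a percent of the image), connected components, a 25–400% disc
area filter, and intensity-weighted centroids over a padded bounding box
(the symmetric soft tails are what give sub-0.1 px accuracy). Correspondence
resolves the lattice orientation from the axis beads on the first plate and
reuses it for the marker-free plates — the scanner geometry is common to all
slices of a stack, mirroring the serial plate digitization of the original
workflow. A bare 4×4 lattice with no markers and no prior orientation is
reported as ambiguous, not guessed.

The calibrated product carries both an absolute pixel scale and a
*scale-correction factor* (recovered ÷ nominal pixel size of the
calibration scans). Registration applies the correction to each target
protocol's own nominal pixel size, so a mapping calibrated on 0.78 mm grid
scans transfers to 0.98 mm fast-sequence trials.

## Registration (automated rotoscoping)

The original technique had a human drag the model until its outline matched
the image. Here the match is scored by zero-normalized cross-correlation
between the observed slice and the model's predicted cross-section —
rendered by *the same* partial-volume operator as the simulator, through
the calibrated mapping — and maximized by Nelder–Mead simplex over the
degrees of freedom the trial physics allows (`tz`, `rx`, `tz`+`tx`, or full
6-DOF), concatenated over both bodies. NCC is amplitude-invariant, which
matters when out-of-plane motion dims a silhouette without moving it.

Numerical choices:

* **DOF masks** mirror the trial design; full 6-DOF exists but is off by
  default for single-plane data, whose out-of-plane DOFs are weakly
  observable.
* **Restarts**: 5 per frame, jittered ±2 mm/±5° (seeded), with an early
  stop once a restart scores ≥ 0.97 — the optimum on these images scores
  ≈ 0.99 even at 3% noise, so later restarts only matter when the first
  basin is wrong.
* **Rotation clamp** at ±45° per axis (soft penalty): the bored cube has
  4-fold symmetry, and trials stay ≤ 20°.
* **Failure** is declared below score 0.5 (empirically, correct
  registrations on this simulator score > 0.9; configurable). A failed
  frame is reported and the series continues, initializing the next frame
  from the last success.
* **Series mode** initializes each frame at the previous frame's solution;
  enumeration order makes consecutive true displacements differ by ≤ 5.4 mm,
  well inside the ±10 mm capture range.
* Frames are processed blind: the ground-truth file is never read.

The joint axes (AJX) are assigned at the registered neutral frame — origin
at the moving cube's centre, axes along the grid/world frame — and can be
saved and reloaded so a second session reuses the first session's axes.
Displacements are the relative pose of the moving body w.r.t. the
stationary body, expressed in the axes frame and differenced against
neutral; rotations use an intrinsic x-y-z Euler convention. The source
experiment never states its Euler sequence or sign conventions (single-axis
trials cannot distinguish them); the convention here is fixed and
documented rather than claimed to be the original's. Signed values are
reported; magnitudes are taken only in the reliability layer. Gimbal-region
extractions (middle angle near 90°) are flagged, not silently returned.

## Reliability statistics

* **CV of a session pair**: `100 · SD(x₁, x₂) / mean(x₁, x₂)` with the
  sample (n−1) SD of the pair, i.e. `|x₁−x₂|/√2` — the convention that
  reproduces the worked 4.44% for the pair (11.5, 10.8). Zero-mean pairs
  (the zero-displacement level) have undefined CVs; they are skipped and
  counted, and the per-level mean CV averages per-trial CVs (averaging
  session means first would contradict the per-trial definition).
  The overall CV is the mean of the per-level mean CVs.
* **ICC(2,1)**: Shrout–Fleiss two-way random effects, single measure,
  absolute agreement, from the two-way ANOVA mean squares; systematic
  between-session bias lowers it, which is the reason this form is chosen
  for test–retest designs. The 95% CI uses the Shrout–Fleiss F-based
  interval (the CI algorithm behind SPSS's output is not documented in the
  source; this choice is stated so cross-checks are interpretable).
* **Bland–Altman**: differences fixed as session 1 − session 2, limits
  bias ± 1.96·SD. Heteroscedasticity is classified from the R² of OLS of
  |differences| on pair means, threshold 0.1, intercept retained.
* **Ratio LOA**: `[(SDdiffs/AVGmeans) × 1.96] × 100`, reported together
  with the systematic-bias component (mean difference, absolute and as a
  percent of AVGmeans).
* **t-tests**: classical dependent t-test between sessions; classical
  equal-variance independent t-test for between-protocol comparisons.

The simulated rater (`simulate_session_pair`) adds an optional bias and
i.i.d. Gaussian error per session; its default error SD of 0.4 mm/deg is
chosen to sit in the range implied by published test–retest SDs for this
kind of manual model matching (≈ 0.3–1 mm). The automated optimizer itself
is deterministic given a seed, so two rotoscoping "sessions" of the same
images agree far better than two human sessions would; human-scale
between-session statistics are studied through the rater model.

## Problem sizes and determinism

The shipped tests and the acceptance script use the full study designs for
displacement recovery (35 + 30 + 20 frames), 100 random matrices for the
ICC oracle, 10⁵ pairs for the Bland–Altman coverage check, 200 replicates
for ICC parameter recovery, and a reduced 4-frame design (2 levels × 2
replicates) for the byte-identity determinism check — determinism does not
depend on problem size, and the small design keeps the check to seconds.
All randomness (placement jitter, imaging noise, optimizer restarts, rater
error) flows from explicit integer seeds; identical configurations produce
byte-identical outputs.

## Known limitations

* The imaging model is geometric; no claim is made about contrast-dependent
  segmentation difficulty on real scanners.
* The NCC-plus-simplex rater is a documented operationalization of a human
  matching process, not a model of human error.
* Single-plane registration cannot observe out-of-plane motion; the
  biplanar mode exists precisely because the orthogonal view supplies the
  missing component.
* The affine-orthographic camera ignores gradient-field geometric
  distortion, which real MR calibration would need to model or correct.
* Accuracy (against ground truth) is assessed on the simulator only;
  the reliability statistics are the quantities the technique is designed
  to report on real data.
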