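# mrikin

Marker-less, MRI-only quantification of rigid-body displacements between two
solid objects — an offline, fully testable implementation of a
morphology-based "rotoscoping" motion-measurement technique aimed at joint
(e.g. inter-vertebral) kinematics, for researchers who want skeletal motion
measurement without the ionizing radiation of fluoroscopy-based methods
(RSA, XROMM and relatives).

The measurement chain is:

1. **Calibrate** the slice-imaging volume from scans of a four-plate bead
   grid (4×4 beads per plate, 20 mm pitch, 30 mm plate spacing): bead
   centroids are digitized, corresponded to the known grid geometry, and a
   Hartley-normalized planar direct linear transformation (an 8-parameter
   plane-to-image homography per plate, the well-posed coplanar analogue of
   the classical 11-parameter DLT) is assembled into an affine-orthographic
   image ↔ world mapping.
2. **Rotoscope**: a 3-D solid model of each object (here, ~40 mm cubes with
   an hourglass bore that mimics a vertebral canal) is registered to its
   silhouette in each single-plane or biplanar MR slice by maximizing the
   zero-normalized cross-correlation

   `NCC(T(θ), I) = <T - T̄, I - Ī> / (‖T - T̄‖ ‖I - Ī‖)`

   between the observed slice `I` and the model's predicted thick-slab
   partial-volume cross-section `T(θ)` over the pose parameters `θ`
   permitted by the trial physics, with a derivative-free simplex search and
   jittered restarts.
3. **Extract displacements** in a joint coordinate system (JCS): the
   relative pose of the moving body w.r.t. the stationary body is expressed
   in an anatomical joint axis frame fixed at the registered neutral frame,
   and reported as translation along z/x (mm) and rotation about x
   (degrees), intrinsic x-y-z Euler convention.
4. **Reliability analysis** of two measurement sessions: per-trial
   between-session CV (`100·|x₁-x₂|/√2 / mean`), ICC(2,1) (two-way random
   effects, single measure, with an F-based 95% CI), a paired t-test,
   Bland–Altman limits of agreement (`bias ± 1.96·SD` of differences) with
   heteroscedasticity classified by the R² of |differences| on means at the
   0.1 threshold, and the ratio LOA `[(SDdiffs/AVGmeans)·1.96]·100`.

Because no public dataset accompanies the original experiment, the package
includes a first-class phantom simulator: implicit-solid cubes and grid
beads rendered as MR-like slices (binary material map + thick-slab partial
volume + Gaussian blur + Gaussian noise, all seeded), with ground-truth
poses kept in separate files so registration can run blinded.

## Worked example

```r
library(mrikin)

# simulate the translation trial design: 0-20 mm in 5 mm steps, 7 trials
# per level, T1-like imaging (0.78125 mm pixels, 5 mm slab, 3% noise)
series <- generate_trial_series("translation_z", seq(0, 20, 5), seed = 101)

# register every frame blind and extract JCS displacements
fit <- rotoscope_series(series, seed = 11)
print(fit)
#> Rotoscoped translation_z series: 35 frames, dof mask 'tz'
#>   scores: min 0.993 / mean 0.993; 0 failed frame(s)

max(abs(fit$displacements$measured - series$true_displacement[, 1]))
#> [1] 0.007652651   # worst-case recovery error, mm (about 1/100 voxel)

# two simulated rater sessions of the same trials, then the full analysis
truth <- series$true_displacement[, 1]
ses <- simulate_session_pair(truth, rater_sigma = 0.4, seed = 7)
rel <- reliability_report(session_pair_data(series$nominal,
                                            ses$session1, ses$session2))
print(rel)
#> Between-session reliability (35 trials)
#> Level    n   Mean+/-SD S1     Mean+/-SD S2     Mean CV(%)
#> 0 mm     7     0.45+/-0.28      0.21+/-0.15       68.79
#> 5 mm     7     5.52+/-0.49      5.05+/-0.37        6.22
#> 10 mm    7    10.16+/-0.35     10.21+/-0.24        2.21
#> 15 mm    7    15.22+/-0.37     14.96+/-0.23        2.08
#> 20 mm    7    19.85+/-0.22     20.30+/-0.08        1.58
#> Overall mean CV: 16.18 %
#> ICC(2,1) = 0.998 (95% CI 0.995-0.999), (2,1) two-way random, single measure
#> Paired t: t = 1.168, p = 0.251
#> Bland-Altman: bias 0.0946, SDdiff 0.4792, 95% LOA [-0.8447, 1.0339]
#>   |diff| vs mean R^2 = 0.024 -> homoscedastic
#> Ratio LOA: bias 0.095 mm (0.93 %), random error +/-9.21 %
```

The per-level rows mirror the reliability-table layout of test–retest
studies: large CVs at the zero level are expected (the CV denominator is the
displacement magnitude itself), while the ICC summarizes agreement across
the whole design. `rotoscope_series` is far more repeatable than a human
rater, so between-session statistics of the automated pipeline are driven by
the simulated-rater model, whose error SD (0.4 mm/deg) is an explicit
parameter.

A thin command-line wrapper over the same functions lives at
`inst/cli/mrikin.R` (subcommands `simulate`, `calibrate`, `rotoscope`,
`analyze`, `all`, each taking `--config`, `--seed`, `--out`).

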