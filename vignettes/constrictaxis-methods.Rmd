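---
title: "constrictaxis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{constrictaxis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`constrictaxis` quantifies single-cell chemotaxis through a single
microfluidic constriction and ships a synthetic-data generator with stored
ground truth. This vignette is the package's account of its science: the
models and their assumptions, the parameters that matter, what the generator
does and does not emulate, and the choices made where the design was
genuinely open.

## 1. The device model

The chamber is a 300 µm long, 5 µm high migration channel with a
pillar-defined constriction whose leading edge sits 100 µm from the cell
inlet and which extends 20 µm along the migration axis; gaps of 3 µm
(narrower than the ~4 µm neutrophil nucleus, forcing nuclear squeezing) or
5 µm (free passage) are the two conditions of interest. Chemoattractant
becomes effectively saturating around 250 µm, where migrating cells arrest.

```{r}
library(constrictaxis)
geom <- device_geometry(gap_width = 3)
classify_position(c(50, 110, 150), geom)   # before / during / after
```

`during` spans the full pillar extent `[100, 120]` µm inclusive, with the
constriction line drawn at the pillar's leading edge — positions are
classified on the cell centroid.

### Gradient

The chemoattractant gradient is modelled as 1D diffusion along the migration
axis with the two 100-µm-high inlet reservoirs idealized as
fixed-concentration boundaries (`C(0) = 0`, `C(L) = C₀`); the steady state is
the linear profile `C₀·x/L`. The pillar's perturbation of the field is
second-order for the establishment question and is not modelled. The solver
is Crank–Nicolson with two backward-Euler half-steps at startup (Rannacher
smoothing): the initial profile is discontinuous at the source boundary, and
plain Crank–Nicolson leaves its high-frequency content ringing instead of
decaying, which delays the apparent establishment by a factor ~2.5.

Parameters (YAML block `device:`):

| parameter | default | units | why |
|---|---|---|---|
| `D_cm2s` | 5e-6 | cm²/s | typical small-peptide diffusivity in water; the source study does not print one |
| `dx_um` | 1 | µm | resolves the 300-µm chamber; must divide its length |
| `dt_s` | 0.5 | s | unconditionally stable; profile error vs the closed form < 0.02% |
| `establish_tol` | 0.10 | fraction of C₀ | our operationalization of "gradient established" (see below) |

How "the gradient establishes" was measured on the original dye images is not
stated anywhere we could follow; this package *defines* establishment as the
first time the profile is within 10% of C₀ of the linear steady state,
uniformly in x. Under that definition the default chamber establishes in 34 s
— comfortably consistent with the published claim of establishment within
15 min, and the time scales as L²/D, so the claim is insensitive to D over
two orders of magnitude. The numerical solution is cross-checked in the test
suite against an independent Fourier eigenfunction expansion (establishment
within 10%, profiles within 1%).

## 2. Kinematics

Tracks are TrackMate-dialect spots tables (`TRACK_ID`, `FRAME`,
`POSITION_T`, `POSITION_X`, `POSITION_Y`, optional `MEAN_INTENSITY`,
`ECCENTRICITY`). Two definitional choices:

* **Directionality** is the confinement ratio, net Euclidean displacement
  over accumulated path length, bounded by 1 — the standard chemotaxis-tool
  meaning, and the only common definition bounded by 1 as the published
  before–after plots are. A signed x-forward-migration index
  (`track_fmi()`) is provided as a companion column.
* **Speed** is path length over elapsed time (µm/min). For uniformly sampled
  tracks this equals the mean frame-to-frame displacement rate, so the
  ambiguity between the two conventions is immaterial here.

The exclusion filter drops tracks whose net final x-displacement is *less
than* 100 µm; the boundary is retained (a strict reading of "less than …
excluded"). The filter is idempotent and logs exclusions.

`split_at_constriction()` uses a first-entry/first-exit rule on the centroid:
`pre` is everything before the first point at or past the pillar's leading
edge, `post` everything from the first point beyond its trailing edge. A cell
oscillating across the entry line is split at its *first* entry — the
disambiguation is arbitrary but deterministic and is checked against a
brute-force frame scan in the tests.

`peri_summary()` computes post-constriction speed and directionality on the
post segment truncated at `saturation_x` (`trim_arrest = TRUE`). Cells
arrest near 250 µm in saturating chemoattractant; they are no longer
chemotaxing, and including the arrest frames would fold the (modelled) speed
decay into the post/pre contrast. The post-constriction Euclidean distance —
whose entire point is how far cells get — always uses the full post segment.
Population post/pre ratios are ratios of medians with seeded bootstrap
percentile CIs (default 2000 resamples); the published significance tests
(ANOVA families) are deliberately out of scope.

## 3. The synthetic cohort generator

### The walk

Each cell updates its heading as

```
theta(t+1) = angle( p * u(theta(t)) + b * x_hat ) + eps,   eps ~ N(0, sigma^2)
```

with persistence `p`, gradient bias `b` toward +x, heading noise `sigma`, and
log-normal step-length jitter (CV 0.3) around `base_speed * dt`. Side walls
reflect; the cell inlet reflects; the chemoattractant end absorbs (cells
arrest rather than bounce). Speed decays linearly to ~0 beyond
`saturation_x`. On first reaching the constriction a cell dwells
`1 + Geometric(1/dwell_mean_frames)` frames (mean 4 — dwell time is not
quantified in the source study; this is a free choice), then traverses the
pillar and continues with post-constriction modifiers. Passage is guaranteed
by default (`pass_prob = 1`): at least 80% of cells squeeze through in the
motivating experiments and the failure mode is not analyzed.

### The stated world

The `control` preset: `base_speed` 12 µm/min, `p` 0.6, `b` 0.35, `sigma`
0.9 rad. These put the pre-constriction median confinement ratio near 0.5 —
realistic for chemotaxing dHL60 neutrophils over 30-s sampling — and give a
net ~6 µm/min advance, so cells cross the constriction around 15–20 min and
reach saturation well inside the 90-min movie. Presets mirror the assay's
qualitative contrasts:

| preset | post speed | post directionality | spike prob | keratocyte prob |
|---|---|---|---|---|
| control | ×1.0 | ×1.1 | 0.5 | 0.5 |
| knockout | ×0.6 | ×0.7 | 0.0 | 0.25 |
| overexpresser | ×1.0 | ×1.3 | 0.6 | 0.7 |

Vesicle counts are negative-binomial (dispersion 5) with means chosen so the
distribution medians equal the phenotype targets (defaults 4 pre, 7 post,
the knockout keeping both — envelope budding does not require the enzyme
whose loss the knockout models); each cell's cortical polarity ratio is
positively coupled to its post-constriction vesicle count for the scatter
summary.

### Calibrating the directionality factor

`post_directionality_factor` is defined on the observable: it is the target
ratio of post- to pre-constriction median confinement ratios. A naive
implementation as a multiplier on persistence cannot honor that definition —
directionality is a nonlinear emergent of persistence, bias, noise *and
segment length* (short pre-segments inflate the confinement ratio upward by
several percent). The generator therefore solves for the post-segment
heading noise `sigma_post` such that its own pilot cohort (fixed internal
seed, 2000 cells, common random numbers across candidate sigmas, measured
with the same filter/segment/median rules as the pipeline) realizes the
stated factor. The pilot function is continuous and monotone in sigma, so
plain bisection converges; results are memoized per phenotype/geometry. The
calibration is deterministic and independent of the user's seed. A factor
requested beyond the attainable ceiling (pre-ratio × factor ≳ 1) is clamped
with a warning.

The speed factor needs no calibration: per-segment speed is linear in the
step scale, so the ratio of medians recovers `post_speed_factor` directly.

### Calcium traces and rendering

Traces are `baseline·(1 + noise_cv·N(0,1))` (floored at 0) plus, with the
phenotype's spike probability, one exponentially decaying spike (default
amplitude 4× baseline, decay 90 s) initiated at a frame where the cell lies
within one cell length (25 µm) past the pillar exit. Spike onset times are
ground truth.

The renderer draws, per frame, cell and nucleus label masks plus nucleus,
membrane, calcium and cortical-marker channels. Shapes: amoeboid cells are
ellipses (axis ratio 1.8) along the polarity axis; keratocyte-like cells are
ellipses (axis ratio 2, eccentricity √(1−1/4) ≈ 0.866) with the major axis
*perpendicular* to it; depolarized cells are discs. A rear-truncated fan
variant of the keratocyte shape exists (`fan_fraction`) but defaults off: a
literal half-disc has eccentricity ≈ 0.57 and would fail the field's own
eccentricity-based classifier. The polarity axis follows the migration axis
with 12° jitter rather than the instantaneous velocity — in the realistic
noise regime the stationary heading SD exceeds 60°, far too broad to define
a morphological axis, and the classifier measures orientation against the
migration axis. The nucleus is a 4-µm disc, compressed to the gap width
(area-preserving) while the cell is inside a constriction narrower than the
nucleus. The cortical channel paints the boundary band defined by the *same*
erosion as the analysis (`band_width` 3 px), so the identity fixture closes
exactly. Overlapping cells are re-jittered with escalating amplitude up to a
retry cap, then error; dense late-movie fields near the arrest region are
physically over-packed, so orchestrated runs render a sparse subset of
cells.

### What the generator does not emulate

No mechanistic chemoattractant/LTB4 signalling (phenotype contrasts are
parameters, not emergent); no tracking errors, gaps, splits or
misassignments; no segmentation noise (masks are ground truth); no
photobleaching, background gradients or PSF; uniform frame rate; passage
guaranteed. A green recovery test therefore establishes that the estimators
are unbiased and correctly aligned on the constriction *given* faithful
tracking and segmentation — not that any upstream tracking pipeline is
accurate.

## 4. Morphology metrics

* **Perimeter** uses an anti-aliased boundary walk: 3×3 box smoothing, then
  the sub-pixel 0.5-level contour (marching squares), whose polygon length is
  the perimeter. Naive pixel-edge counting inflates a disc's perimeter ~27%
  (form factor 0.62); weighted chain codes can fix the disc or the square but
  not both. This estimator keeps the digital disc's form factor at ~0.99 and
  the square's at ~π/4 simultaneously, and is rotation-stable to < 0.02.
* **Solidity** counts pixels against the rasterized pixel-center convex
  hull, which is exactly 1 for convex digitized shapes. The corner-hull area
  ratio understates small ellipses by up to ~10% — enough to push a true
  ellipse below the 0.9 classifier threshold.
* **Orientation** is folded into [0°, 90°] against the migration/fiber axis:
  the ">45°" classifier wording implies an unsigned acute angle.
* **NE folds** are convexity defects (hull minus mask), opened by one pixel
  to discard the 1-px slivers any smooth digitized boundary produces, then
  counted above `min_defect_area`. An intensity-ridge variant was considered
  and rejected: the original segmentation recipe is not printed, and the
  convexity definition is parameter-light and testable against constructed
  fixtures.
* **Keratocyte classification** is the strict triple rule
  (orientation > 45°, eccentricity > 0.75, solidity > 0.9); thresholds are
  config-overridable. `keratocyte_fraction()` votes per cell over its
  post-constriction frames and excludes border-clipped objects.

## 5. Intensity metrics

* **Peri-constriction windows**: one cell length (25 µm) immediately before
  the pillar's leading edge and immediately after its trailing edge. The
  post window is exit-anchored; whether the published shading abuts the near
  or far pillar face is not resolvable from the figures, and the exit anchor
  is the conservative choice (it cannot include in-pillar frames). Fold
  change uses window means; a peak variant is exposed.
* **Spikes**: local maxima above a rolling-median baseline plus 5×MAD
  (robust; the motivating description says only "prominent"), with a
  minimum separation and a post-constriction flag.
* **Cortex/cytosol**: boundary band of 3 px by erosion; the cytosol excludes
  the nucleus when a nucleus mask is supplied, and both ratios are reported.
* **NE enrichment**: the nuclear-envelope band is ±2 px around the nuclear
  boundary; the "total nuclear" compartment is the union of nucleoplasm and
  NE band (i.e. the dilated nucleus), so the three reported fractions are
  exactly additive.
* **Mander's M1/M2** with Kapur maximum-entropy thresholds when none are
  given.

## 6. Numerical choices, sentinels and degenerate inputs

* Establishment never reached → `NA_real_` sentinel with a message, never an
  exception; empty analysis regions → `NA_real_`; zero-variance correlation
  → `NA_real_`; a stationary track has directionality 0 with a warning.
* Nobody entering/crossing the constriction reports crossing fraction 0 and
  empty post statistics.
* Calibration root-finding: bisection on [0.02, 3] rad, tolerance 1e-3, with
  clamping and a warning outside the attainable range.
* Bootstrap CIs are percentile CIs, seeded; ties in medians follow R's
  default (mean of central order statistics).
* All randomness flows from explicit `seed` arguments; identical seeds give
  bit-identical cohorts, traces, frames and summary JSON.

## 7. Known limitations

* The gradient is 1D; pillar-resolved 2D diffusion and flow are out of scope.
* The walk model is kinematic (heading-update), not force-based; it exposes
  the phenotype contrasts the analysis measures and nothing more.
* Directionality calibration targets the *median ratio* at the configured
  cohort size and track lengths; at very different n or segment lengths the
  realized ratio can drift by a few percent (finite-length bias).
* The renderer's morphologies are parametric (ellipses/discs); it validates
  metric and classifier implementations, not segmentation robustness on
  irregular real shapes.
* 3D metrics assume a single connected nucleus per stack and report the
  mid-plane slice for elongation.
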