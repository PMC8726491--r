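---
title: "Opportunistic osteoporosis screening from proximal-femur CT attenuation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Opportunistic osteoporosis screening from proximal-femur CT attenuation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(femhu)
```

## The screening problem

Abdominal-pelvic CT scans acquired for unrelated indications image the
proximal femur at no extra dose or cost. Because CT attenuation (Hounsfield
units, HU) of bone falls as mineral density falls and marrow fat rises, simple
attenuation indexes measured on those scans can flag patients who should be
referred for DXA. `femhu` implements the full analysis chain for two
measurement strategies and the statistics needed to compare them:

* **3D_Femur**: a volume of interest covering the whole proximal femur, from
  the head down to the inferior margin of the lesser trochanter, obtained by
  HU-bounded 3D region growing plus marrow filling.
* **2D_coronal**: the largest circular ROI drawn around the femoral neck's 3D
  central point on the true-coronal reformatted plane, touching the outer
  cortex.

On each region three indexes are computed: **mean-HU**; **HUHA_Fat**, the
percentage of voxels below 0 HU (fatty marrow); and **HUHA_Bone**, the
percentage at or above 126 HU (mineralised bone). The band edges are fixed
conventions of the HU-histogram analysis: 0 HU separates fat from water-like
tissue, and the 126 HU edge is inclusive (`x >= 126` counts as bone). The mid
band is reported as the remainder, so the three percentages sum to exactly
100 by construction.

Osteoporosis status is defined densitometrically: `T-score <= -2.5`
(inclusive) is osteoporosis; `-2.5 < T < -1.0` osteopenia; `T >= -1.0` normal.
The binary screening target merges the latter two as non-osteoporosis.

## The phantom cohort

No patient scans ship with the package; a seeded synthetic cohort stands in
for them. It emulates a screening population of 430 women (96 osteoporotic,
334 not), with group moments

| group | age (y) | BMD (g/cm^2) |
|---|---|---|
| osteoporosis | 78.5 ± 8.7 | 0.57 ± 0.06 |
| non-osteoporosis | 61.7 ± 10.2 | 0.84 ± 0.12 |

BMD is the sampled quantity. Each group draws from a Gaussian truncated to its
side of the diagnostic boundary; the location parameter is solved so that the
*truncated* mean equals the configured mean (plain truncation would shift the
osteoporosis BMD mean by about a quarter standard deviation). T-scores are
then derived as `(BMD - ref_mean) / ref_sd`. The reference constants default
to `ref_mean = 1.13`, `ref_sd = 0.18` g/cm^2 — chosen so that the configured
group BMD means land on the corresponding group T-score means (-3.1 and
-1.6), making the cohort table internally consistent; densitometer reference
populations are vendor-specific and the defaults are configurable. A
consequence of deriving T from BMD is that every reported correlation with
T-score has the same sign structure as the correlation with BMD.

### Phantom anatomy

Each subject's CT volume is a union of analytic solids — a spherical head, a
tapering frustum neck at a 130° neck-shaft angle, a cylindrical shaft, and
ellipsoidal greater/lesser trochanter bosses — so that every landmark (head
centre, neck axis, neck waist, inferior lesser-trochanter margin) has
closed-form ground truth. A 2 mm cortical shell at 1200 HU surrounds a
marrow-space interior; the shell is sealed at the shaft ends and the neck
base so the marrow cavity is topologically enclosed, which is what makes
hole-filling after region growing recover the full bone. The default grid is
120 × 80 × 96 voxels at 0.67 × 0.67 × 1 mm — the in-plane resolution and
slice thickness of thin-slice abdominal-pelvic CT reconstructions. Only the
left femur is rendered (the measured side in the emulated protocol);
laterality is a flag.

### Tissue composition and the BMD coupling

The interior is a per-voxel categorical mixture of trabecular bone (300 HU),
red marrow (50 HU) and fat (-80 HU) rather than a continuous blend: with
planted category labels in the ground-truth channel, the expected HUHA
fractions are known exactly, and on noise-free renders the measured fractions
equal the planted ones voxel-for-voxel. BMD drives the mixture through two
linear monotone maps over BMD 0.40–1.20 g/cm^2: the marrow fat fraction falls
from 0.75 to 0.10, and the target interior mean attenuation rises from -20 to
180 HU (the trabecular-voxel probability is solved from that target and
clipped to feasibility). The study the package emulates established that such
monotone coupling exists but quantified it only through observed
correlations, so the coupling strength here is a modelling choice: strong
enough that the diagnostic layer has signal to detect, and documented as a
tunable, not an empirical constant. Additive Gaussian noise (default SD 12
HU, a typical soft-kernel reconstruction noise level) is applied everywhere
and the result clipped to the 12-bit CT range.

What the phantom deliberately does **not** model: scanner physics (beam
hardening, scatter, iterative-reconstruction texture), cortical thinning with
age, intertrochanteric trabecular architecture (principal compressive/tensile
groups, Ward's triangle), adjacent bones at the hip joint, and contrast
enhancement. Passing tests on phantoms therefore demonstrate that the
*measurement and statistics machinery* is correct and that the pipeline
recovers planted monotone structure — not that the specific AUCs or cutoffs
transfer to clinical scans.

### Anatomical variation in the pipeline

Phantom geometry is identical for every subject given one `phantom_spec()`.
The pipeline multiplies the linear dimensions by a per-subject scale factor
(SD 4%, clamped to ±10%) so that region sizes vary across subjects; without
it the interobserver reliability of Total Area/Volume would be degenerate
(zero between-subject variance). The factor is drawn from the per-subject
seed stream, so runs remain exactly reproducible.

## Segmentation

Region growing returns the maximal connected component of voxels within an HU
band containing the seed, under 6- or 26-connectivity (default 26, matching
interactive 3D editing tools). The band default `[126, 3071]` starts at the
bone-band edge: it captures the cortex and trabecular lattice, after which
`fill_interior()` adds every background component not 6-connected to the grid
boundary — the marrow cavity. 26-connected foreground pairs with 6-connected
background, the standard duality that keeps diagonal shell voxels sealing.
The commercial tool the workflow emulates is interactive and its parameters
undocumented; the defaults reproduce its *outcome* (a solid proximal femur)
deterministically.

The VOI's inferior boundary is a flat axial plane at the inferior margin of
the lesser trochanter, inclusive. Detection scans slices from inferior to
superior and returns the first whose in-plane width exceeds the shaft
baseline width (median of the five most inferior non-empty slices) by a
prominence of 2 mm — about three in-plane pixels, large enough to ignore
voxelisation jitter and small enough to catch the boss within a slice or two
of its true margin. A manual override bypasses detection, and a featureless
shaft (no trochanter) is an error instructing the caller to use it.

## Neck frame and reformation

The femoral head centre is the argmax of an anisotropic chamfer distance
transform (the centre of the maximal inscribed sphere). The neck axis is
initialised from the head centre toward the centroid of the bone more than
1.5 head-radii away, then refined by iterating two exact observations about
the geometry: the head centre lies on the neck axis, and the centroid of the
cross-section at the neck waist (the minimal-area plane) also lies on it. At
each iteration the waist is re-located along the current axis by a
minimal-area scan (nearest-neighbour mask sampling on a 1.6 mm grid, in-plane
cutoff 1.4 × the equivalent waist radius to exclude the trochanters), and the
axis is redirected from the head centre through the waist centroid. Four
iterations suffice; a final scan at half the step and 0.5 mm axial
resolution localises the waist, whose restricted centroid is the neck centre
— the "3D central point". The test suite verifies, over 50 seeded phantoms
with anatomical variation, that the axis is recovered within 5°, the centre
within 3 mm and the cut plane within 2 slices. A flat area profile (a
straight cylinder) is accepted with the waist at mid-scan; a profile with no
positive interior minimum (an isolated sphere — no neck) is an error.

The true-coronal plane contains the neck axis; the second in-plane direction
is chosen so the plane normal is as close to the anteroposterior axis as the
neck axis allows. Note one convention: `in_plane_u` *is* the neck axis, and
orthonormality holds for `{in_plane_u, in_plane_v, plane_normal}` — a plane
containing the axis cannot be spanned by two vectors orthogonal to it. HU is
resampled by trilinear interpolation (monotone, no overshoot across the 0 and
126 HU band edges, exact on affine fields); masks by nearest neighbour.
Samples outside the volume are `NA` and poison any ROI that overlaps them
(an explicit error rather than a silently truncated mean). Default plane:
80 × 80 mm at 0.67 mm pixels.

## ROI construction

The 2D ROI is the largest circle around the neck centre that touches, without
crossing, the outer cortical boundary: its radius is the distance to the
nearest non-femur pixel centre, and membership is by pixel centre strictly
inside the radius. Cortical bone up to the outer boundary is therefore
*inside* the ROI, which raises HUHA_Bone relative to a marrow-only ROI — a
property of the emulated measurement convention, kept deliberately.

## Statistics

All of the statistical layer is implemented in the package and cross-checked
in the test suite against independent oracles (pair enumeration, trapezoidal
ROC area, `aov()` mean squares, `pROC`, exhaustive permutation):

* **AUC** is the Mann-Whitney pair statistic (ties 1/2) with a DeLong
  structural-component variance for the 95% CI, truncated to [0, 1]. Indexes
  are oriented before ranking: HUHA_Fat is `positive_if_high`; mean-HU and
  HUHA_Bone are `positive_if_low`.
* **Youden cutoffs** scan thresholds at observed score values only, so a
  reported cutoff is always an attainable data value; positivity is
  `score <= cutoff` for low-oriented indexes and `score > cutoff` for
  high-oriented ones, matching the "≤ x HU" / "> x %" reporting convention.
  Ties in J break toward higher sensitivity, then the smaller-magnitude
  cutoff.
* **PPV/NPV** come from integer confusion matrices reconstructed from
  sensitivity/specificity and group sizes, rounding half away from zero.
  This same arithmetic links a published table's sensitivity/specificity
  columns to its predictive-value columns at the study prevalence
  (96/430 = 22.3%).
* **DeLong's test** compares correlated AUCs through placement-value
  covariances; comparing an index against any strictly monotone transform of
  itself is degenerate by construction and reported as z = 0, p = 1 with a
  flag.
* **Spearman correlation** is the Pearson correlation of mid-ranks; its CI
  uses the Fisher z-transform with the variance-inflated standard error
  `sqrt((1 + rho^2/2) / (n - 3))`, a documented choice among several in use.
  Magnitude categories: < 0.20 negligible, then weak, moderate, strong,
  ≥ 0.80 very strong.
* **ICC(A,1)** — two-way model, absolute agreement, single measure — is
  computed from the ANOVA decomposition
  `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`, with the F-based CI
  using Satterthwaite degrees of freedom. Categories: < 0.50 poor, 0.50–0.75
  moderate, 0.76–0.90 good, > 0.90 excellent (the conventional reading; one
  published statement of these bins contains an obvious typo at the upper
  bin). Identical rater columns yield ICC 1 with a degenerate CI.
* **Group comparisons** default to the two-sided Mann-Whitney test (the
  emulated analysis did not name its test; the rank test is the conservative
  default for skewed clinical variables), switchable to Welch's t.
* **Box-plot summaries** are five-number summaries with linear-interpolation
  quartiles (R type 7).

## The reliability experiment

Two "observers" measure the same 50 rendered scans. Observer subjectivity is
modelled as jitter on exactly the knobs a human controls: the region-growing
seed point (±2 voxels, which is inconsequential because any seed inside the
cortex grows the same component), the detected cut plane (±1 slice), and the
2D ROI centre (±2 mm in-plane, which changes the inscribed circle's radius
and contents). These magnitudes are calibration knobs, not measured values —
the emulated study attributes 2D unreliability to cross-section selection
and ROI drawing but does not quantify either. With them, 3D-VOI ICCs exceed
2D-ROI ICCs for every variable at equal jitter, reproducing the qualitative
ordering reported for the two strategies; with zero jitter every ICC is
exactly 1, the degenerate sanity check.

## Numerical choices and problem sizes

* Percentage triplets sum to exactly 100 (mid band is the remainder);
  reports round half away from zero to one decimal, full precision is kept
  internally.
* HU is stored as floating point; all volumes are validated to
  [-1024, 3071].
* World coordinates are LPS millimetres, voxel indices 0-based, coordinates
  carried by voxel centres; NIfTI's RAS affine and DICOM's LPS geometry are
  converted at the I/O boundary.
* Every random quantity flows from one root seed through an exact integer
  hash (multiplier small enough that products stay below 2^53), so
  identical configurations reproduce reports bit-for-bit.
* Test and demonstration cohorts use the default 120 × 80 × 96 grid
  (~0.9 M voxels, ~0.6 s per subject end-to-end); the full 430-subject
  pipeline plus the 50-scan reliability experiment runs in minutes on one
  core. These sizes were chosen so the whole analysis is convenient to
  re-run from scratch.

## Known limitations

* The phantom's BMD-attenuation coupling is linear and strong; real cohorts
  have overlap, comorbidities and scanner effects, so simulated AUCs are
  upper bounds, not predictions.
* Cut-plane detection assumes the lesser trochanter is the first width
  prominence above the shaft; severely atypical anatomy would need the
  manual override.
* The DICOM reader supports uncompressed single-frame explicit-VR
  little-endian CT series only — the common export for research use; there
  is no DICOM writing.
* Cortical and trabecular compartments are not analysed separately (the
  emulated workflow measures the whole region).
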