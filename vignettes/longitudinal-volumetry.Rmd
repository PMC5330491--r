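---
title: "Longitudinal glioblastoma volumetry: models, phantoms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal glioblastoma volumetry: models, phantoms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliovol)
```

## The problem

In the MRI follow-up of glioblastoma, two tumor compartments are tracked:
the contrast-enhancing volume (CV) on gadolinium-enhanced T1 MPRage, a
surrogate for proliferating tumor with a disrupted blood-brain barrier,
and the FLAIR-hyperintense volume (FV), which also contains non-enhancing
tumor and edema and normally contains CV. Given semi-automated 3D
segmentations of both compartments at every time point, there are two
natural ways to quantify change between consecutive scans:

* **absolute deltas** — `dCV = CV2 − CV1` (likewise dFV), here normalised
  by the *least significant change* (LSC) of the measurement method; and
* **regional, segmentation-based subtractions** — after rigid registration
  of the scan pair, the volume of voxels present in the follow-up mask but
  absent at baseline (`sCV`, `sFV`), which preserves localisation but
  inherits registration and re-segmentation error.

The package implements both determinants, a consensus-label model of how
"disease progression" is adjudicated in practice, and a logistic
mixed-effects classifier that asks which determinant actually predicts
progression. Everything is exercised end to end on synthetic longitudinal
phantoms with known ground truth.

## The classifier

For follow-up $j$ of patient $i$ with progression label $y_{ij}$:

$$\operatorname{logit} P(y_{ij} = 1) = \beta_0 + \beta^\top x_{ij} + b_i,
\qquad b_i \sim N(0, \sigma_b^2)$$

with $x_{ij}$ a subset of (dCV, dFV, sCV, sFV). The fit uses the Laplace
approximation (`lme4::glmer`); P-values are two-sided Wald tests, matching
the estimate / standard error / P reporting convention of clinical mixed
models. Model comparison is by grouped 5-fold cross-validation: all of a
patient's follow-ups share a fold, so the random intercept cannot leak
across the split, and held-out patients are scored with the
population-level linear predictor ($b_i = 0$) because a new patient has no
estimated intercept. The competing out-of-fold ROC curves are compared
with DeLong's test for correlated ROC curves (structural-component
covariance of the paired AUCs), and each model's cross-validated accuracy
(threshold 0.5) is tested against the no-information rate with an exact
upper-tail binomial test.

Two AUC conventions circulate for cross-validated ROC analysis — the AUC of
all pooled out-of-fold predictions and the mean of per-fold AUCs — and
published reports do not always say which one they use. `compare_models()`
emits both (`auc` and `auc_fold_mean`); the pooled value is the primary
one.

## LSC correction

The semi-automated segmentation method's single-rater precision error is
35.2% for CV and 14.4% for FLAIR; a between-scan change smaller than this
fraction of the tumor volume is within measurement noise. Deltas are
divided by the *absolute LSC* — the LSC fraction times a reference volume —
so that a corrected |delta| of 1 marks exactly the significance boundary.
The reference volume is not uniquely defined by that prescription; this
package defaults to the **baseline volume** (scan *t*), which makes the
corrected delta scale invariant and exactly $(V_2 - V_1)/(f \cdot V_1)$,
and offers the pair mean as `reference = "mean"` for sensitivity analysis.
Post-resection scans can have zero enhancing volume; the reference is then
floored (`floor_ml`, default one 1 mm³ voxel) and the value flagged rather
than returned infinite.

## Segmentation

The commercial two-plane brush tool this workflow emulates is proprietary
and undocumented, so the package implements a transparent stand-in with
the same interaction contract: one axial and one coronal 2D seed contour
in, one 3D mask out. The intensity band is the seed region's mean ±
`tolerance_k` (default 2.5) standard deviations with inclusive bounds; the
band is flooded by 6-connected (face-adjacent) region growing from the
seed union; fully enclosed cavities are then filled — repairing interior
voxels dropped by intensity noise without ever moving the outer boundary —
playing the role of the "rough 3D interpolation". Structures a rater would
exclude (necrosis, cavities, vessels) are handled the same way a rater
handles them: they fall outside the intensity band, or are removed with
`manual_edit()`. No claim is made that outputs match the commercial tool
voxel for voxel; the defaults are surfaced as configuration, not as
reverse-engineered constants. A volume cap (default 500 ml) aborts
runaway growth, the signature of a tolerance band that leaked into
background.

## Registration

Scan pairs are aligned rigidly (6 degrees of freedom) by maximising
normalised mutual information, which is robust across MPRage/FLAIR
contrasts. Both volumes are pre-smoothed with a radius-1 box filter
(voxel noise carries no alignment information), initialisation is by
centre-of-mass translation with a small multi-start, and optimisation is
Nelder-Mead with one restart (the restart rebuilds the simplex, which
matters for the weakly curved rotation directions). Masks are resampled
with nearest-neighbour interpolation so labels stay strictly binary and
volumes remain well defined. The similarity score (NMI − 1, which is 0
for independent images) supports the manual-review gate of clinical
practice: pairs scoring below `score_threshold` (default 0.002, set
between the scores of structurally matched phantom pairs, ~0.005 at
default noise, and independent noise pairs, ~0.001) are flagged
unregistered and should be excluded from regional subtractions — they
still contribute absolute deltas, which need no registration.

## Consensus labels

Each scan carries a 0–5 rating (0 initial diagnosis, 1 immediate
postoperative, 2 regression, 3 stable, 4 uncertain progression,
5 progression). The multidisciplinary consensus (MC) is resolved
hierarchically: histopathology when available, else the tumor-board
decision, else the radiologic consensus (RC). Dichotomization maps 5 to
"progression", 2–3 to "no", and excludes 0–1 from modeling: immediate
postoperative scans combine hard-to-segment signal alterations with a
volume collapse that would dominate the fit. Whether category 4
("uncertain progression", e.g. possible pseudo-progression) counts as
progression is genuinely ambiguous in clinical practice; the package
defaults to "no" and exposes `progression_categories = c(4, 5)` as the
inclusive alternative — the two runs differ only in category-4 rows, which
the pipeline tests verify. Inter-rater agreement uses Cohen's kappa with
the convention that two constant, identical raters get kappa 1 (chance
agreement is then also perfect and the usual formula is 0/0).

## The phantom generator

`phantom_spec()` defaults describe the emulated study conditions: 30
patients with 3–12 scans each (at least three follow-ups being the
inclusion criterion); scan 1 is the initial diagnosis, scan 2 the
postoperative MRI with a large resection-driven volume collapse, and later
scans progress with probability 0.75 per follow-up (multiplicative CV
growth factor 2.0) or stay stable/regress. Baseline CV is log-normal
(median 6.6 ml pre-operatively) with a log-normal FV/CV ratio; after the
postoperative collapse this yields cross-scan medians near 3 ml CV and
50 ml FV with quartiles spanning roughly 0.3–11 ml and 25–90 ml,
matching the descriptive statistics of a real 30-patient cohort at this
scale. Volumes are capped (45 ml CV, 150 ml FV) because intracranial
anatomy bounds tumor size and the phantom grid must contain the lesion.

Two design choices matter for what the downstream tests can show:

* **Progression labels couple primarily to CV change.** Ratings are
  generated from the progression event (progressed scans are rated 5, or
  4 in 15% of cases; stable scans 3 with occasional uncertain 4s;
  shrinking scans 2), two raters read them with a confusion probability
  of 0.13 (reproducing inter-rater kappa near .84), disagreements are
  resolved by a consensus session that picks one reading, and
  histopathology (16.4% of scans) or tumor-board labels (42%) override
  RC in the MC hierarchy. With the default growth effect this makes dCV
  the genuinely informative determinant; with `growth_effect = 1` the
  labels decouple from the volumes entirely, giving a null generator for
  size calibration.
* **Regional subtractions carry extra error by construction.** Table-mode
  sCV/sFV equal the true new-tumor volume plus a misregistration term
  (lesion cross-section times a random residual offset, scaled by
  `misregistration_sd` = 1.5 mm/deg) plus re-segmentation jitter scaled
  with the lesion's surface area (volume^(2/3), since boundary error is a
  shell phenomenon). These scales were calibrated once so the cohort's
  median sCV (~1.5 ml) and sFV (~17 ml) sit at realistic levels; they are
  what makes the delta-versus-subtraction comparison non-trivial.

Rendered phantoms (`render_phantom_images()`) realise the same cohort as
3D volumes: lobulated lesions built from 2–5 overlapping ellipsoids with
a sinusoidal boundary perturbation (spheres would make segmentation
trivially easy), piecewise-constant intensities (background 20, FLAIR
compartment 30 on the MPRage channel, lesion 100) plus Gaussian noise
(SD 12 against an 80-unit contrast) and a low-frequency three-wave
background texture that moves rigidly with the patient pose — a stand-in
for the brain structure that actually anchors rigid registration, without
which rotations are nearly unidentifiable from a single central lesion.
Consecutive scans differ by small cumulative rigid offsets (SD 1.5 mm and
degrees). An optional dark fluid cavity adjacent to, but outside, the
truth masks emulates the resection cavities and cysts a rater must not
segment. Ground-truth volumes are recomputed from the voxelised masks, so
mask and volume agree exactly; they track the tabular trajectories to
within the ~2% voxelisation tolerance.

What the phantoms deliberately do **not** model: MRI physics (bias
fields, Rician noise, partial volume), brain anatomy, nonrigid
deformation (brain shift), and therapy-related enhancement dynamics.
Passing phantom tests therefore demonstrates the correctness and
calibration of the algorithms under controlled conditions, not clinical
performance on real images.

## Numerical conventions

* Volumes in ml throughout; voxel sizes in mm (default isotropic 1 mm);
  mask volume is the exact voxel count times voxel volume.
* Voxel indices are 1-based in R; world coordinates are
  `voxel_size * (index − 1) + origin` mm. Transforms use the pull-back
  convention (target world coordinates mapped into source world
  coordinates), serialised as plain-text 4×4 matrices.
* Intensity band bounds are inclusive; region-growing connectivity is
  6-neighbour; ROC ties count one half; quartiles use linear
  interpolation (R type 7).
* Cross-validation folds where the mixed model cannot be trained
  (single-class outcome or convergence failure) fall back to a plain
  logistic fit, then to the smoothed training class rate, and the
  fallback is recorded per observation.
* DeLong's test with identical score orderings has zero variance of the
  AUC difference; P is defined as 1 and flagged degenerate.

## Problem sizes

The shipped tests validate mask algebra on 1,000 random 16³ mask pairs
against an exhaustive voxel-loop oracle, DeLong variances against
10,000-replicate stratified bootstraps on 20-observation instances, AUC
against brute-force pair counting up to 500 observations, coefficient
recovery on 100 replicates of 200 patients × 5 pairs, test size on 200
null-generator cohorts, the headline delta-versus-subtraction ordering on
50 study-scale cohorts, and segmentation precision on 50 rendered
phantom scans — sizes chosen to give stable Monte-Carlo rates while
keeping a full run on one CPU comfortably under half an hour.

## A worked run

```{r, eval = FALSE}
cohort <- simulate_cohort_table(phantom_spec(seed = 1))
report <- run_pipeline(cohort, seed = 1)
print(report)
```

The report prints the descriptive cohort table (median and quartiles of
CV, dCV, sCV, FV, dFV, sFV), the two kappa statistics, the four-predictor
mixed-model coefficient table, both models' cross-validated AUC and
accuracy with binomial P-values, and DeLong's comparison. On default
cohorts the delta model's AUC exceeds the subtraction model's and dCV is
the dominant predictor — the qualitative behaviour the generator is
designed to make recoverable, mirroring what is reported for real
longitudinal glioblastoma cohorts.

## Known limitations

* The segmentation stand-in shares the workflow, not the internals, of
  the commercial brush tool; absolute agreement with it cannot be tested.
* MI registration on phantoms reaches ~0.1°/0.1 mm accuracy without
  noise but degrades to ~2° rotational error at default noise; regional
  subtraction results at default noise inherit this, which is part of
  what the comparison is about.
* The generator's rating model is deliberately simple (confusion to
  adjacent categories); it reproduces agreement levels, not radiologists'
  actual error structure.
* Wald P-values from the Laplace approximation are mildly
  anti-conservative at 30-patient scale; the null-generator test tracks
  this and keeps the empirical size at the nominal boundary.
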