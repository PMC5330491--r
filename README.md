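# gliovol

Longitudinal volumetry for glioblastoma follow-up: which volumetric change
measure actually detects progressive disease?

In MRI follow-up of glioblastoma, two tumor compartments are segmented at
every time point — the contrast-enhancing volume (**CV**, gadolinium T1
MPRage) and the FLAIR-hyperintense volume (**FV**, which contains CV). Two
competing determinants quantify change between consecutive scans *t* and
*t+1*:

* **LSC-corrected absolute deltas**
  `dCV = (CV2 − CV1) / (f_CV · CV1)` (and likewise dFV), where
  `f_CV = 0.352` and `f_FV = 0.144` are the single-rater *least
  significant change* fractions of the semi-automated segmentation method:
  |dCV| > 1 marks a change beyond measurement precision.
* **Regional, segmentation-based subtractions**
  `sCV = |M2 \ M1|` ml, the volume of voxels present in the rigidly
  registered follow-up mask `M2` but absent from the baseline mask `M1`
  (localised "new tumor", never negative).

The package provides the full pipeline around this question, exercised end
to end on synthetic longitudinal phantoms with known ground truth:

* `phantom_spec()` / `simulate_cohort_table()` / `render_phantom_images()`
  — a study-scale phantom cohort generator (30 patients, 3–12 scans,
  postoperative collapse, CV-driven progression) in tabular and full 3D
  NIfTI-able image/mask form;
* `seed_contour()` / `segment_semiauto()` / `manual_edit()` — two-plane
  seeded 3D region-growing segmentation with volume readout
  (`mask_volume_ml()`);
* `register_rigid()` / `resample_mask()` — rigid mutual-information
  registration with a review gate and nearest-neighbour mask resampling;
* `delta_volume()` / `lsc_correct()` / `regional_subtraction()` /
  `change_records()` — the change determinants;
* `cohens_kappa()` / `resolve_mc()` / `dichotomize()` — consensus ratings
  (0–5 scale), the hierarchical multidisciplinary consensus
  (histopathology > tumor board > radiologic consensus) and the binary
  progression endpoint;
* `fit_glmm()` / `crossvalidate()` / `roc_auc()` / `delong_test()` /
  `binomial_accuracy_test()` / `compare_models()` — the logistic
  mixed-effects classifier

  logit P(progression_ij) = β₀ + βᵀ x_ij + b_i,  b_i ~ N(0, σ_b²)

  with patient-grouped 5-fold cross-validation, DeLong's test for the
  correlated out-of-fold ROC curves, and exact binomial accuracy tests
  against the no-information rate;
* `run_pipeline()` — the orchestrated table-mode analysis with a report
  bundle, driven step by step by the numbered scripts under `analysis/`.

See `vignettes/longitudinal-volumetry.Rmd` for the models, the phantom
design and every numerical convention.

## Worked example

```r
library(gliovol)
cohort <- simulate_cohort_table(phantom_spec(seed = 1))
report <- run_pipeline(cohort, seed = 1)
print(report)
```

```
== Longitudinal volumetry report (seed 1) ==
  variable   n  median      q25     q75
1    cv_ml 156  3.0299   1.0036   8.781
2   dcv_ml 126  0.2386  -0.9280   1.782
3   scv_ml 126  1.1446   0.4882   4.266
4    fv_ml 156 57.4177  27.1874 121.308
5   dfv_ml 126  0.0000 -11.1619   9.409
6   sfv_ml 126 13.8747   8.5480  25.815
Inter-rater kappa 0.828; RC vs MC kappa 0.908; 30 pairs excluded (ratings 0/1)
Progression model comparison (96 follow-ups, NIR = 0.615)
  delta model (dCV+dFV):        AUC 0.798, accuracy 0.771, binomial P 0.0008
  subtraction model (sCV+sFV):  AUC 0.590, accuracy 0.573, binomial P 0.8276
  DeLong z = 2.835, P = 0.0046
Joint four-predictor model:
         term estimate std_error  p_value
1 (Intercept) -0.70660   0.43941 0.107821
2         dcv  0.56499   0.21860 0.009749
3         dfv  0.45260   0.20199 0.025043
4         scv  0.14278   0.06925 0.039215
5         sfv -0.03229   0.01671 0.053393
```

Reading it: the cohort's 156 scans have median CV ≈ 3 ml and FV ≈ 57 ml
(the small CV median reflects the included postoperative scans); of the
126 consecutive scan pairs, 30 end at initial/postoperative scans and are
excluded, leaving 96 modeled follow-ups with a 61.5% progression rate (the
no-information rate). The delta-volume model separates progressive from
non-progressive follow-ups clearly better than the regional-subtraction
model (cross-validated AUC .80 vs .59; only the delta model's accuracy
beats the no-information rate, binomial P = .0008), and the LSC-corrected
contrast-enhancement delta dCV carries the smallest P-value in the joint
model — the qualitative conclusion the generator is built to make
recoverable.

The numbered scripts under `analysis/` run the same study as separate
stages (simulate → segment phantoms → register/subtract → change metrics
and consensus → progression model), each writing its tables under
`results/`; set `GLIOVOL_SEED` to change the cohort seed.

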