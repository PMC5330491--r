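Package: gliovol
Title: Longitudinal Glioblastoma Volumetry and Progression Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for longitudinal volumetric follow-up of glioblastoma:
    a synthetic phantom generator for longitudinal MRI cohorts with known
    ground truth, semi-automated region-growing segmentation of
    contrast-enhancing (CV) and FLAIR-hyperintense (FV) tumor compartments,
    rigid mutual-information registration with nearest-neighbour mask
    resampling, least-significant-change (LSC) corrected volume deltas and
    regional segmentation-based subtractions, consensus rating utilities
    (Cohen's kappa, hierarchical multidisciplinary labeling), and a logistic
    mixed-effects progression classifier with grouped cross-validation,
    ROC/AUC, DeLong's test for correlated ROC curves and an exact binomial
    accuracy test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    RNifti,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
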