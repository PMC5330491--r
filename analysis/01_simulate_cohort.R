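#!/usr/bin/env Rscript

# Stage 1: generate the synthetic longitudinal cohort.
#
# Draws the default study-scale phantom cohort (30 glioblastoma patients,
# 3-12 scans each: initial diagnosis, postoperative collapse, then
# follow-ups with CV-driven progression) and writes the per-scan volume
# table, the two raters' 0-5 ratings and the multidisciplinary-consensus
# sources to results/.

library(gliovol)

seed <- as.integer(Sys.getenv("GLIOVOL_SEED", "1"))
cohort <- simulate_cohort_table(phantom_spec(seed = seed))
paths <- write_cohort_csv(cohort, "results")

print(cohort)
s <- cohort$scans
cat(sprintf("median CV %.2f ml (IQR %.2f-%.2f), median FV %.2f ml (IQR %.2f-%.2f)\n",
            median(s$cv_ml), quantile(s$cv_ml, .25), quantile(s$cv_ml, .75),
            median(s$fv_ml), quantile(s$fv_ml, .25), quantile(s$fv_ml, .75)))
cat("wrote:", paste(basename(paths), collapse = ", "), "\n")
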