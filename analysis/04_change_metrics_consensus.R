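#!/usr/bin/env Rscript

# Stage 4: change determinants and consensus labeling.
#
# Builds one record per consecutive scan pair carrying the four volumetric
# determinants — LSC-corrected absolute deltas (dCV, dFV) and regional
# subtraction volumes (sCV, sFV) — then resolves the multidisciplinary
# consensus rating per scan (histopathology > tumor board > radiologic
# consensus) and dichotomizes it into the progression endpoint. Also
# reports inter-rater agreement of the radiologic ratings.

library(gliovol)

seed <- as.integer(Sys.getenv("GLIOVOL_SEED", "1"))
cohort <- simulate_cohort_table(phantom_spec(seed = seed))

records <- change_records(cohort$scans, lsc_params())
records <- label_records(records, cohort$mc_sources)

ra <- cohort$ratings[cohort$ratings$rater == "a", ]
rb <- cohort$ratings[cohort$ratings$rater == "b", ]
kap <- cohens_kappa(ra$category, rb$category)
mc <- resolve_mc(cohort$mc_sources$histo, cohort$mc_sources$board,
                 cohort$mc_sources$rc)

dir.create("results", showWarnings = FALSE)
write.csv(records, "results/change_records_labeled.csv", row.names = FALSE)

cat(sprintf("%d scan pairs, %d modeled (ratings 0/1 excluded)\n",
            nrow(records), sum(!is.na(records$progression))))
cat(sprintf("inter-rater kappa %.3f; RC vs MC kappa %.3f\n",
            kap, cohens_kappa(cohort$mc_sources$rc, mc$mc)))
cat(sprintf("MC tiers: histopathology %.1f%%, tumor board %.1f%%, RC %.1f%%\n",
            100 * mean(mc$tier == 1), 100 * mean(mc$tier == 2),
            100 * mean(mc$tier == 3)))
print(summarize_cohort(cohort$scans, records), digits = 3)
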