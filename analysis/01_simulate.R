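#!/usr/bin/env Rscript
# Stage 1: generate the default calibrated synthetic cohort (n = 1888)
# and write it under results/cohort/ for the downstream stages.
suppressPackageStartupMessages(library(refluxr))

seed <- 20110511L
cfg <- default_sim_config(seed = seed)
cohort <- generate_cohort(cfg)
write_cohort(cohort$patients, cohort$scores, "results/cohort")

cat("Simulated", nrow(cohort$patients), "patients (seed", seed, ")\n")
cat("Daily score rows:", nrow(cohort$scores), "\n")
tab <- function(x) round(100 * prop.table(table(x)), 1)
cat("\nGender (%):\n"); print(tab(cohort$patients$gender))
cat("\nOesophagitis (%):\n"); print(tab(cohort$patients$oesophagitis))
cat("\nGeography (%):\n"); print(tab(cohort$patients$geography))
cat("\nBaseline HADS anxiety mean:",
    round(mean(cohort$patients$hads_anxiety_baseline), 2),
    " depression mean:",
    round(mean(cohort$patients$hads_depression_baseline), 2), "\n")
cat("\nCohort written to results/cohort/\n")
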