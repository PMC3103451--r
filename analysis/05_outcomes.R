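#!/usr/bin/env Rscript
# Stage 5: concordance of score-defined response with patient
# satisfaction and investigator assessment, and GERDyzer QoL summaries.
suppressPackageStartupMessages(library(refluxr))

co <- read_cohort("results/cohort")
responders <- utils::read.csv("results/responders.csv")
st_w4 <- responders[responders$horizon_day == 28, ]
st_w8 <- responders[responders$horizon_day == 56, ]

conc <- list(
  satisfaction_w8 = crosstab_assessment(co$patients, st_w8, "satisfaction", "week8"),
  investigator_w8 = crosstab_assessment(co$patients, st_w8, "investigator", "week8"),
  satisfaction_w4 = crosstab_assessment(co$patients, st_w4, "satisfaction", "week4"),
  investigator_w4 = crosstab_assessment(co$patients, st_w4, "investigator", "week4")
)
for (ct in conc[c("satisfaction_w8", "investigator_w8")]) {
  print(ct)
  ds <- discordance_summary(ct)
  cat(sprintf(
    "  top-category non-responders: %d/%d (%.1f%%); responders in bottom category: %.1f%%\n\n",
    ds$top_category_nonresponders, ds$top_category_n,
    100 * ds$top_category_nonresponder_share,
    100 * ds$responders_in_bottom_category_share))
}
jsonlite::write_json(
  lapply(conc, function(ct) list(
    assessment_kind = ct$assessment_kind, visit = ct$visit,
    counts = as.data.frame.matrix(ct$counts), categories = rownames(ct$counts),
    discordance = discordance_summary(ct))),
  "results/concordance.json", auto_unbox = TRUE, digits = NA, na = "null")

q <- qol_summary(co$patients, st_w8)
cat("GERDyzer group means (day 0 / week 4 / week 8):\n")
print(q$means, digits = 3)
cat("\nBaseline-to-visit changes and between-group tests:\n")
print(q$changes, digits = 3)
print(q$tests, digits = 3)
jsonlite::write_json(q, "results/qol_summary.json", auto_unbox = TRUE,
                     digits = NA, na = "null")
cat("\nSummaries written to results/concordance.json and results/qol_summary.json\n")
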