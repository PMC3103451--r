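#!/usr/bin/env Rscript
# Stage 2: classify every patient with the 1.6 / 3-consecutive-day rule
# at the week-4 and week-8 horizons; summarise rates by subgroup.
suppressPackageStartupMessages(library(refluxr))

co <- read_cohort("results/cohort")
st_w4 <- classify_cohort(co$scores, responder_rule(horizon_day = 28L))
st_w8 <- classify_cohort(co$scores, responder_rule(horizon_day = 56L))
utils::write.csv(rbind(st_w4, st_w8), "results/responders.csv",
                 row.names = FALSE, na = "")

pct <- function(st, ids = NULL) {
  if (!is.null(ids)) st <- st[st$patient_id %in% ids, ]
  round(100 * cohort_response_rate(st), 1)
}
cat("Overall response: week 4", pct(st_w4), "% / week 8", pct(st_w8), "%\n")
p <- co$patients
erd <- p$patient_id[p$oesophagitis %in% c("A", "B", "C", "D")]
nerd <- p$patient_id[p$oesophagitis == "NERD"]
cat("Week 8 by oesophagitis: ERD", pct(st_w8, erd),
    "% vs NERD", pct(st_w8, nerd), "%\n")
cat("Week 8 by gender: male",
    pct(st_w8, p$patient_id[p$gender == "male"]), "% vs female",
    pct(st_w8, p$patient_id[p$gender == "female"]), "%\n")
cat("Week 8 by geography:\n")
for (g in unique(p$geography)) {
  cat(sprintf("  %-15s %.1f%%\n", g, pct(st_w8, p$patient_id[p$geography == g])))
}
cat("Responder table written to results/responders.csv\n")
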