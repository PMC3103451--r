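#!/usr/bin/env Rscript
# Stage 3: dual prediction-level search over baseline (day 0) and the
# first 10 treatment days, 0.01-step grid, for GI, WSO and total scores.
suppressPackageStartupMessages(library(refluxr))

co <- read_cohort("results/cohort")
responders <- utils::read.csv("results/responders.csv")
st_w8 <- responders[responders$horizon_day == 56, ]

ps <- select_best_day(co$scores, st_w8, days = 1:10, step = 0.01,
                      min_group = 30L)
print(ps)
utils::write.csv(format_prediction_table(ps$per_day),
                 "results/prediction_per_day.csv", row.names = FALSE)
jsonlite::write_json(
  list(best = format_prediction_table(ps$best),
       baseline = format_prediction_table(ps$baseline)),
  "results/prediction_summary.json", auto_unbox = TRUE, digits = NA,
  na = "null")
cat("\nPrediction tables written to results/prediction_*.{csv,json}\n")
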