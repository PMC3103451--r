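# Independent oracles and fixture builders shared across test files.

# Brute-force responder oracle: enumerate every candidate run of
# `run_length` consecutive calendar days and check each day directly.
brute_responder <- function(day, score, threshold = 1.6, run_length = 3L,
                            strict = TRUE, window_start = 1L, horizon = 56L) {
  for (start in window_start:(horizon - run_length + 1L)) {
    ok <- TRUE
    for (d in start:(start + run_length - 1L)) {
      i <- which(day == d)
      if (length(i) != 1 || is.na(score[i])) { ok <- FALSE; break }
      pass <- if (strict) score[i] < threshold else score[i] <= threshold
      if (!pass) { ok <- FALSE; break }
    }
    if (ok) return(start + run_length - 1L)
  }
  NA_integer_
}

# random daily series with missingness, on a GI-like scale
random_series <- function(n_days = 56, p_missing = 0.15, max_score = 6) {
  day <- sort(sample(0:56, n_days))
  score <- round(stats::runif(n_days, 0, max_score), 2)
  score[stats::runif(n_days) < p_missing] <- NA
  data.frame(day = day, gi = score)
}

# per-level recount by direct subsetting (no sorting tricks)
slow_rates <- function(scores, flags, level) {
  low <- scores <= level
  list(
    response_rate = if (sum(low) > 0) mean(flags[low]) else NA_real_,
    nonresponse_rate = if (sum(!low) > 0) mean(!flags[!low]) else NA_real_,
    n_low = sum(low), n_high = sum(!low)
  )
}

# exhaustive level-grid search mirroring the dual-level definition
slow_optimize <- function(scores, flags, step, score_max, min_group) {
  levels <- (0:floor(score_max / step + 1e-9)) * step
  best_r <- -Inf; L <- NA; rL <- NA; nL <- NA
  best_n <- -Inf; U <- NA; rU <- NA; nU <- NA
  for (lv in levels) {
    r <- slow_rates(scores, flags, lv + step * 1e-6)
    if (r$n_low >= min_group && !is.na(r$response_rate) &&
        r$response_rate >= best_r) {
      # >= keeps the largest level attaining the maximum
      best_r <- r$response_rate; L <- lv; rL <- r$response_rate; nL <- r$n_low
    }
    if (r$n_high >= min_group && !is.na(r$nonresponse_rate) &&
        r$nonresponse_rate > best_n) {
      # > keeps the smallest level attaining the maximum
      best_n <- r$nonresponse_rate; U <- lv; rU <- r$nonresponse_rate
      nU <- r$n_high
    }
  }
  list(response_level = L, response_rate = rL, n_low = nL,
       nonresponse_level = U, nonresponse_rate = rU, n_high = nU)
}

# minimal patient table for outcomes tests
make_patients <- function(n, satisfaction_w8 = "very",
                          investigator_w8 = "well",
                          gerdyzer = c(50, 30, 20)) {
  data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    satisfaction_w8 = rep_len(satisfaction_w8, n),
    investigator_w8 = rep_len(investigator_w8, n),
    satisfaction_w4 = rep_len(satisfaction_w8, n),
    investigator_w4 = rep_len(investigator_w8, n),
    gerdyzer_day0 = rep_len(gerdyzer[1], n),
    gerdyzer_w4 = rep_len(gerdyzer[2], n),
    gerdyzer_w8 = rep_len(gerdyzer[3], n),
    stringsAsFactors = FALSE
  )
}

make_statuses <- function(patient_id, is_responder, horizon = 56L) {
  data.frame(patient_id = patient_id, horizon_day = horizon,
             is_responder = is_responder,
             run_end_day = ifelse(is_responder, 3L, NA_integer_),
             stringsAsFactors = FALSE)
}

# full ReQuest item set at given intensity/frequency
request_items <- function(intensity = 0, frequency = 0) {
  dims <- c("acid", "upper_abdominal", "lower_abdominal", "nausea",
            "sleep", "other", "wellbeing")
  data.frame(
    dimension = dims,
    intensity = rep_len(intensity, length(dims)),
    frequency = ifelse(dims == "wellbeing", NA_integer_,
                       rep_len(frequency, length(dims))),
    stringsAsFactors = FALSE
  )
}

# cache the default calibrated cohort for tests that share it
.fixtures <- new.env(parent = emptyenv())
default_cohort <- function(seed = 1L) {
  key <- paste0("cohort_", seed)
  if (is.null(.fixtures[[key]])) {
    co <- generate_cohort(default_sim_config(seed = seed))
    co$statuses_w4 <- classify_cohort(co$scores, responder_rule(horizon_day = 28L))
    co$statuses_w8 <- classify_cohort(co$scores, responder_rule(horizon_day = 56L))
    .fixtures[[key]] <- co
  }
  .fixtures[[key]]
}

# toy patient table with the columns encode_factors() derives from
toy_cohort <- function(n, oesophagitis = "A", gender = "female",
                       geography = "Western Europe", h_pylori = "negative",
                       ibs = "no", bmi = 25, age = 50, anx = 8, dep = 5) {
  data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    age = rep_len(age, n), bmi = rep_len(bmi, n),
    gender = rep_len(gender, n), geography = rep_len(geography, n),
    h_pylori = rep_len(h_pylori, n), oesophagitis = rep_len(oesophagitis, n),
    ibs_flag = rep_len(ibs, n), smoking = "never",
    hads_anxiety_baseline = rep_len(anx, n),
    hads_depression_baseline = rep_len(dep, n),
    stringsAsFactors = FALSE
  )
}

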