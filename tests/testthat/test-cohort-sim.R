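test_that("generation is bit-reproducible given the seed", {
  cfg <- default_sim_config(n_patients = 300L, seed = 7L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c_ <- generate_cohort(default_sim_config(n_patients = 300L, seed = 8L))
  expect_false(identical(a$patients, c_$patients))
})

test_that("the cohort respects the documented shapes and score ranges", {
  co <- default_cohort()
  expect_equal(nrow(co$patients), 1888L)
  # day 0 present for every patient
  d0 <- co$scores[co$scores$day == 0, ]
  expect_setequal(d0$patient_id, co$patients$patient_id)
  expect_true(all(co$scores$day >= 0 & co$scores$day <= 56))
  expect_true(all(co$scores$gi >= 0 & co$scores$gi <= 30.77))
  expect_true(all(co$scores$wso >= 0 & co$scores$wso <= 15.51))
  expect_equal(co$scores$total, co$scores$gi + co$scores$wso)
  expect_true(all(co$patients$hads_anxiety_baseline %in% 0:21))
  expect_true(all(co$patients$bmi > 0))
  expect_true(all(co$patients$oesophagitis %in%
                    c("NERD", "A", "B", "C", "D", "missing")))
})

test_that("covariate marginals converge to their configured targets", {
  checks <- 0; within3se <- 0
  for (s in 1:5) {
    co <- default_cohort(seed = s)
    cm <- default_sim_config()$covariate_marginals
    obs <- list(
      gender = table(co$patients$gender),
      geography = table(co$patients$geography),
      h_pylori = table(co$patients$h_pylori),
      oesophagitis = table(co$patients$oesophagitis),
      smoking = table(co$patients$smoking)
    )
    for (nm in names(obs)) {
      for (lev in names(cm[[nm]])) {
        p <- cm[[nm]][[lev]]
        se <- sqrt(p * (1 - p) / 1888)
        got <- as.numeric(obs[[nm]][lev]) / 1888
        if (is.na(got)) got <- 0
        checks <- checks + 1
        if (abs(got - p) <= 3 * se) within3se <- within3se + 1
      }
    }
  }
  expect_gte(within3se / checks, 0.95)
})

test_that("a stronger ERD effect widens the ERD/NERD responder gap", {
  gaps <- sapply(c(0.2, 0.55, 0.9), function(b_erd) {
    cfg <- default_sim_config(seed = 77L,
                              response_model = list(erd = b_erd))
    co <- generate_cohort(cfg)
    st <- classify_cohort(co$scores, responder_rule(horizon_day = 56L))
    erd <- co$patients$patient_id[co$patients$oesophagitis %in%
                                    c("A", "B", "C", "D")]
    nerd <- co$patients$patient_id[co$patients$oesophagitis == "NERD"]
    cohort_response_rate(st[st$patient_id %in% erd, ]) -
      cohort_response_rate(st[st$patient_id %in% nerd, ])
  })
  expect_true(all(diff(gaps) > 0))
})

test_that("zero severity and zero noise make everyone a responder", {
  cfg <- default_sim_config(
    n_patients = 100L, seed = 5L,
    trajectory_params = list(baseline_mean_responder = 0,
                             baseline_mean_nonresponder = 0,
                             noise_sd = 0, wso_noise_sd = 0))
  co <- generate_cohort(cfg)
  expect_true(all(co$scores$gi == 0))
  st <- classify_cohort(co$scores, responder_rule())
  expect_true(all(st$is_responder))
})

test_that("a null response model yields null covariate effects", {
  # identical trajectory dynamics in both classes, intercept-only response
  # model: any univariate coefficient should be centred at zero
  set.seed(55)
  coefs <- sapply(1:20, function(s) {
    cfg <- default_sim_config(
      n_patients = 500L, seed = 1000L + s,
      response_model = c(intercept = 0.9),
      trajectory_params = list(
        baseline_mean_nonresponder = 6.0, baseline_sd_nonresponder = 3.2,
        asymptote_frac_nonresponder = 0.04,
        tau_meanlog_nonresponder = log(9.2), tau_sdlog_nonresponder = 0.67))
    co <- generate_cohort(cfg)
    st <- classify_cohort(co$scores, responder_rule(horizon_day = 56L))
    fit <- univariate_screen(co$patients, st, "erd_nerd")$erd_nerd
    fit$coefficients$estimate[2]
  })
  expect_lt(abs(mean(coefs)), 2 * sd(coefs) / sqrt(20))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(default_sim_config(n_patients = 0), "n_patients")
  expect_error(
    default_sim_config(covariate_marginals = list(gender = c(female = 0.7,
                                                             male = 0.7))),
    "covariate_marginals\\$gender")
  expect_error(default_sim_config(trajectory_params = list(noise_sd = -1)),
               "noise_sd")
  expect_error(
    default_sim_config(trajectory_params = list(missing_day_prob = 1.5)),
    "missing_day_prob")
  expect_error(
    default_sim_config(assessment_misclassification = list(
      satisfaction = rbind(responder = c(very = 0.5, fairly = 0.2, not = 0.2),
                           non_responder = c(very = 0.3, fairly = 0.3,
                                             not = 0.4)))),
    "satisfaction")
  expect_error(default_sim_config(response_model = c(wingspan = 1)),
               "response_model")
})

test_that("HADS and satisfaction structure follows the class split", {
  co <- default_cohort()
  flag <- setNames(co$statuses_w8$is_responder, co$statuses_w8$patient_id)
  r <- as.logical(flag[co$patients$patient_id])
  # responders' anxiety falls to the normal band by week 8; non-responders'
  # stays above it
  expect_lt(mean(co$patients$hads_anxiety_w8[r]), 7)
  expect_gt(mean(co$patients$hads_anxiety_w8[!r]), 7)
  # baseline anxiety is in the 'suggestive' band for both groups
  expect_gte(mean(co$patients$hads_anxiety_baseline[r]), 8)
  expect_gte(mean(co$patients$hads_anxiety_baseline[!r]), 8)
  # depression stays in the normal range throughout
  expect_lt(mean(co$patients$hads_depression_baseline), 7)
  expect_lt(mean(co$patients$hads_depression_w8), 7)
  # satisfaction is strongly but imperfectly concordant with response
  ct <- crosstab_assessment(co$patients, co$statuses_w8, "satisfaction",
                            "week8")
  ds <- discordance_summary(ct)
  expect_gt(ds$top_category_nonresponder_share, 0.05)
  expect_lt(ds$top_category_nonresponder_share, 0.25)
  expect_lt(ds$responders_in_bottom_category_share, 0.05)
})

test_that("cohorts round-trip losslessly through the CSV files", {
  co <- generate_cohort(default_sim_config(n_patients = 40L, seed = 3L))
  dir <- withr::local_tempdir()
  write_cohort(co$patients, co$scores, dir)
  back <- read_cohort(dir)
  expect_equal(back$patients, co$patients)
  expect_equal(back$scores, co$scores)

  # a 2-patient cohort: 2 patient rows, at most 2 x 57 score rows
  co2 <- generate_cohort(default_sim_config(n_patients = 2L, seed = 4L))
  d2 <- withr::local_tempdir()
  write_cohort(co2$patients, co2$scores, d2)
  expect_equal(nrow(utils::read.csv(file.path(d2, "patients.csv"))), 2L)
  expect_lte(nrow(utils::read.csv(file.path(d2, "daily_scores.csv"))), 114L)

  # inconsistent inputs are rejected
  rogue <- co$scores
  rogue$patient_id[1] <- "P99999"
  expect_error(write_cohort(co$patients, rogue, withr::local_tempdir()),
               "unknown patient_id")
})
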