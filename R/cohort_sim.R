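# Synthetic GORD cohort generator.
#
# Emulates the statistical structure the downstream analyses assume: an
# 1888-patient pragmatic-trial cohort with the published covariate
# marginals, a latent responder class drawn from a logistic model on the
# baseline factors, daily ReQuest GI/WSO trajectories (exponential decay
# toward a class-dependent asymptote plus truncated Gaussian noise),
# class-conditional HADS and GERDyzer follow-up, and satisfaction /
# investigator categories drawn from misclassification matrices
# conditioned on the run-rule classifier outcome at each visit.
#
# Default parameters are calibrated so that, under the 1.6 / 3-day rule,
# the simulated week-4 and week-8 response rates and the ERD-subgroup
# week-8 rate reproduce the published 58.9% / 71.2% / 75.5%.

GEOGRAPHY_LEVELS <- c("Western Europe", "South America", "Asia", "Canada",
                      "South Africa", "Australia")

#' Default simulation configuration
#'
#' Covariate marginals follow the published baseline tables of the
#' 1888-patient cohort; the response-model coefficients, decay time
#' constants and misclassification matrices are the packaged calibrated
#' defaults (see the methods vignette for how they were chosen).
#'
#' @param n_patients cohort size (default 1888).
#' @param seed integer RNG seed.
#' @param ... named overrides for any top-level field; list fields are
#'   merged element-wise.
#' @return object of class `sim_config`.
#' @export
default_sim_config <- function(n_patients = 1888L, seed = 1L, ...) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    seed = as.integer(seed),
    covariate_marginals = list(
      gender = c(female = 978, male = 910) / 1888,
      geography = stats::setNames(
        c(894, 352, 326, 124, 100, 92) / 1888, GEOGRAPHY_LEVELS),
      h_pylori = c(positive = 687, negative = 1070, intermediate = 98,
                   missing = 33) / 1888,
      oesophagitis = c(NERD = 694, A = 680, B = 381, C = 97, D = 23,
                       missing = 13) / 1888,
      smoking = c(never = 1179, former = 360, current = 349) / 1888,
      ibs = c(no = 0.66, yes = 0.24, unknown = 0.10)
    ),
    # gender-linked covariate structure (female minus male differences);
    # marginals above are preserved exactly in expectation
    gender_confounding = list(
      nerd_delta = 0.30,       # NERD more prevalent in women
      ibs_yes_delta = 0.18,    # IBS symptoms more prevalent in women
      anxiety_delta = 1.6      # higher baseline anxiety in women
    ),
    age_mean = 47.0, age_sd = 14.3,
    bmi_mean = 26.4, bmi_sd = 4.8,
    hads_anxiety_mean = 8.5, hads_anxiety_sd = 3.8,
    hads_depression_mean = 5.3, hads_depression_sd = 3.5,
    # latent responder propensity: logit scale; bmi standardized, HADS
    # total centred at its configured mean, geography vs Western Europe
    response_model = c(
      intercept = 0.81,
      erd = 0.55,
      male = 0.10,
      bmi_z = 0.15,
      hads_total_c = -0.045,
      ibs_yes = -0.45,
      ibs_unknown = -0.15,
      geo_south_america = 0.0,
      geo_asia = -0.54,
      geo_canada = 0.0,
      geo_south_africa = 0.69,
      geo_australia = -0.49
    ),
    trajectory_params = list(
      baseline_mean_responder = 6.0, baseline_sd_responder = 3.2,
      baseline_mean_nonresponder = 8.8, baseline_sd_nonresponder = 4.4,
      asymptote_frac_responder = 0.04, asymptote_frac_nonresponder = 0.5,
      tau_meanlog_responder = log(9.2), tau_sdlog_responder = 0.67,
      tau_meanlog_nonresponder = log(30), tau_sdlog_nonresponder = 0.3,
      noise_sd = 0.8,
      wso_ratio_mean = 0.504, wso_ratio_sdlog = 0.25, wso_noise_sd = 0.5,
      missing_day_prob = 0.03
    ),
    hads_trajectory = list(
      anxiety_drop_w8_responder = 2.2, anxiety_drop_w8_nonresponder = 1.3,
      depression_drop_w8_responder = 1.2,
      depression_drop_w8_nonresponder = 0.6,
      noise_sd = 1.5
    ),
    gerdyzer = list(
      mean_responder = c(day0 = 44, w4 = 22, w8 = 14),
      mean_nonresponder = c(day0 = 53, w4 = 41, w8 = 36),
      noise_sd = 12
    ),
    assessment_misclassification = list(
      satisfaction = rbind(
        responder = c(very = 0.7106, fairly = 0.2814, not = 0.0080),
        non_responder = c(very = 0.2849, fairly = 0.3651, not = 0.3500)
      ),
      investigator = rbind(
        responder = c(well = 0.8482, fairly = 0.1418, not = 0.0100),
        non_responder = c(well = 0.5699, fairly = 0.3101, not = 0.1200)
      )
    )
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks marginals sum to one, probabilities lie in [0, 1], sizes and
#' standard deviations are admissible.  Errors name the offending field.
#'
#' @param config a `sim_config`.
#' @return the config, invisibly, if valid.
#' @export
validate_sim_config <- function(config) {
  fail <- function(field, msg) {
    stop("invalid simulation config: ", field, " ", msg, call. = FALSE)
  }
  if (!is.numeric(config$n_patients) || length(config$n_patients) != 1 ||
      is.na(config$n_patients) || config$n_patients < 1) {
    fail("n_patients", "must be a positive integer")
  }
  for (nm in names(config$covariate_marginals)) {
    p <- config$covariate_marginals[[nm]]
    if (any(is.na(p)) || any(p < 0 | p > 1)) {
      fail(paste0("covariate_marginals$", nm), "has probabilities outside [0,1]")
    }
    if (abs(sum(p) - 1) > 1e-9) {
      fail(paste0("covariate_marginals$", nm),
           sprintf("must sum to 1 (got %.12f)", sum(p)))
    }
  }
  for (nm in c("age_sd", "bmi_sd", "hads_anxiety_sd", "hads_depression_sd")) {
    if (config[[nm]] < 0) fail(nm, "must be >= 0")
  }
  tp <- config$trajectory_params
  if (tp$noise_sd < 0) fail("trajectory_params$noise_sd", "must be >= 0")
  if (tp$missing_day_prob < 0 || tp$missing_day_prob > 1) {
    fail("trajectory_params$missing_day_prob", "must be in [0,1]")
  }
  for (nm in c("baseline_mean_responder", "baseline_mean_nonresponder",
               "baseline_sd_responder", "baseline_sd_nonresponder")) {
    if (tp[[nm]] < 0) fail(paste0("trajectory_params$", nm), "must be >= 0")
  }
  for (nm in c("asymptote_frac_responder", "asymptote_frac_nonresponder")) {
    if (tp[[nm]] < 0 || tp[[nm]] > 1) {
      fail(paste0("trajectory_params$", nm), "must be in [0,1]")
    }
  }
  mis <- config$assessment_misclassification
  for (nm in names(mis)) {
    m <- mis[[nm]]
    if (any(m < 0 | m > 1)) {
      fail(paste0("assessment_misclassification$", nm),
           "has probabilities outside [0,1]")
    }
    if (any(abs(rowSums(m) - 1) > 1e-9)) {
      fail(paste0("assessment_misclassification$", nm),
           "rows must sum to 1")
    }
  }
  bad_beta <- setdiff(names(config$response_model),
                      names(default_beta_template()))
  if (length(bad_beta)) {
    fail("response_model", paste("has unknown coefficient(s):",
                                 paste(bad_beta, collapse = ", ")))
  }
  invisible(config)
}

default_beta_template <- function() {
  c(intercept = 0, erd = 0, male = 0, bmi_z = 0, hads_total_c = 0,
    ibs_yes = 0, ibs_unknown = 0, geo_south_america = 0, geo_asia = 0,
    geo_canada = 0, geo_south_africa = 0, geo_australia = 0)
}

#' Read a simulation configuration from a JSON file
#'
#' The document mirrors the `sim_config` fields; absent fields keep their
#' packaged defaults.
#'
#' @param path JSON file.
#' @param seed optional seed override.
#' @return `sim_config`.
#' @export
read_sim_config <- function(path, seed = NULL) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(seed)) raw$seed <- seed
  do.call(default_sim_config, c(
    list(n_patients = raw$n_patients %||% 1888L, seed = raw$seed %||% 1L),
    raw[setdiff(names(raw), c("n_patients", "seed"))]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# gamma draw parameterised by mean/sd, degenerate cases handled
.rgamma_ms <- function(n, mean, sd) {
  if (mean <= 0) return(rep(0, n))
  if (sd <= 0) return(rep(mean, n))
  shape <- (mean / sd)^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

.rcat <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Generate a synthetic cohort
#'
#' Draws covariates from the configured marginals (with the configured
#' gender-linked differences in NERD, IBS and anxiety prevalence), a
#' latent responder class from the logistic response model, daily GI/WSO
#' score trajectories with MCAR missing days, visit-level HADS and
#' GERDyzer values, and satisfaction / investigator categories
#' conditioned on the run-rule classifier outcome at week 4 and week 8.
#' Deterministic given `config$seed`.
#'
#' @param config a [default_sim_config()] (or modified) configuration.
#' @return list with `patients` (one row per patient) and `scores`
#'   (long-format daily GI/WSO/total scores, days 0-56).
#' @export
generate_cohort <- function(config = default_sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  cm <- config$covariate_marginals
  gc_ <- config$gender_confounding

  patient_id <- sprintf("P%05d", seq_len(n))
  gender <- .rcat(n, cm$gender)
  female <- gender == "female"
  w_f <- cm$gender[["female"]]
  geography <- .rcat(n, cm$geography)
  smoking <- .rcat(n, cm$smoking)
  h_pylori <- .rcat(n, cm$h_pylori)

  # oesophagitis: missing independent of gender; NERD vs ERD conditional
  # on gender with the marginal preserved; grade split among ERD
  p_miss <- cm$oesophagitis[["missing"]]
  p_nerd_obs <- cm$oesophagitis[["NERD"]] / (1 - p_miss)
  nerd_f <- p_nerd_obs + (1 - w_f) * gc_$nerd_delta
  nerd_m <- p_nerd_obs - w_f * gc_$nerd_delta
  if (nerd_f < 0 || nerd_f > 1 || nerd_m < 0 || nerd_m > 1) {
    stop("invalid simulation config: gender_confounding$nerd_delta ",
         "pushes a conditional NERD probability outside [0,1]")
  }
  grades <- cm$oesophagitis[c("A", "B", "C", "D")]
  grades <- grades / sum(grades)
  oesophagitis <- character(n)
  is_miss <- stats::runif(n) < p_miss
  p_nerd_i <- ifelse(female, nerd_f, nerd_m)
  is_nerd <- !is_miss & (stats::runif(n) < p_nerd_i)
  oesophagitis[is_miss] <- "missing"
  oesophagitis[is_nerd] <- "NERD"
  is_erd <- !is_miss & !is_nerd
  oesophagitis[is_erd] <- .rcat(sum(is_erd), grades)

  # IBS flag, gender-conditional with preserved marginal
  yes_f <- cm$ibs[["yes"]] + (1 - w_f) * gc_$ibs_yes_delta
  yes_m <- cm$ibs[["yes"]] - w_f * gc_$ibs_yes_delta
  if (min(yes_f, yes_m) < 0 || max(yes_f, yes_m) + cm$ibs[["unknown"]] > 1) {
    stop("invalid simulation config: gender_confounding$ibs_yes_delta ",
         "pushes a conditional IBS probability outside [0,1]")
  }
  u <- stats::runif(n)
  p_yes_i <- ifelse(female, yes_f, yes_m)
  ibs_flag <- ifelse(u < p_yes_i, "yes",
                     ifelse(u < p_yes_i + cm$ibs[["unknown"]], "unknown", "no"))

  age <- as.integer(pmax(18, round(stats::rnorm(n, config$age_mean, config$age_sd))))
  bmi <- pmax(14, stats::rnorm(n, config$bmi_mean, config$bmi_sd))
  anx_mean_i <- config$hads_anxiety_mean +
    ifelse(female, (1 - w_f), -w_f) * gc_$anxiety_delta
  hads_anx <- as.integer(pmin(21, pmax(0, round(
    stats::rnorm(n, anx_mean_i, config$hads_anxiety_sd)))))
  hads_dep <- as.integer(pmin(21, pmax(0, round(
    stats::rnorm(n, config$hads_depression_mean, config$hads_depression_sd)))))

  # latent responder class from the logistic response model
  beta <- default_beta_template()
  beta[names(config$response_model)] <- config$response_model
  hads_total <- hads_anx + hads_dep
  hads_centre <- config$hads_anxiety_mean + config$hads_depression_mean
  lp <- beta[["intercept"]] +
    beta[["erd"]] * as.numeric(oesophagitis %in% c("A", "B", "C", "D")) +
    beta[["male"]] * as.numeric(!female) +
    beta[["bmi_z"]] * (bmi - config$bmi_mean) / config$bmi_sd +
    beta[["hads_total_c"]] * (hads_total - hads_centre) +
    beta[["ibs_yes"]] * as.numeric(ibs_flag == "yes") +
    beta[["ibs_unknown"]] * as.numeric(ibs_flag == "unknown") +
    beta[["geo_south_america"]] * as.numeric(geography == "South America") +
    beta[["geo_asia"]] * as.numeric(geography == "Asia") +
    beta[["geo_canada"]] * as.numeric(geography == "Canada") +
    beta[["geo_south_africa"]] * as.numeric(geography == "South Africa") +
    beta[["geo_australia"]] * as.numeric(geography == "Australia")
  latent_responder <- stats::runif(n) < stats::plogis(lp)

  # daily score trajectories
  tp <- config$trajectory_params
  b <- ifelse(latent_responder,
              .rgamma_ms(n, tp$baseline_mean_responder, tp$baseline_sd_responder),
              .rgamma_ms(n, tp$baseline_mean_nonresponder,
                         tp$baseline_sd_nonresponder))
  b <- pmin(b, REQUEST_GI_MAX)
  f_asym <- ifelse(latent_responder, tp$asymptote_frac_responder,
                   tp$asymptote_frac_nonresponder)
  tau <- ifelse(latent_responder,
                stats::rlnorm(n, tp$tau_meanlog_responder, tp$tau_sdlog_responder),
                stats::rlnorm(n, tp$tau_meanlog_nonresponder,
                              tp$tau_sdlog_nonresponder))
  wso_ratio <- tp$wso_ratio_mean * stats::rlnorm(n, 0, tp$wso_ratio_sdlog)

  days <- 0:56
  nd <- length(days)
  decay <- exp(-outer(days, tau, "/"))                     # nd x n
  mean_gi <- t(b * f_asym + (b * (1 - f_asym)) * t(decay)) # nd x n
  gi <- mean_gi + stats::rnorm(nd * n, 0, tp$noise_sd)
  gi <- pmin(pmax(gi, 0), REQUEST_GI_MAX)
  mean_wso <- sweep(mean_gi, 2, wso_ratio, "*")
  wso <- mean_wso + stats::rnorm(nd * n, 0, tp$wso_noise_sd)
  wso <- pmin(pmax(wso, 0), REQUEST_WSO_MAX)

  miss <- matrix(stats::runif(nd * n) < tp$missing_day_prob, nd, n)
  miss[1, ] <- FALSE   # day 0 always present
  gi[miss] <- NA_real_
  wso[miss] <- NA_real_

  scores <- data.frame(
    patient_id = rep(patient_id, each = nd),
    day = rep(days, times = n),
    gi = as.vector(gi),
    wso = as.vector(wso),
    stringsAsFactors = FALSE
  )
  scores$total <- scores$gi + scores$wso
  scores <- scores[!is.na(scores$gi), ]
  rownames(scores) <- NULL

  # classifier outcome at the two visits drives the assessments
  st_w4 <- classify_cohort(scores, responder_rule(horizon_day = 28L))
  st_w8 <- classify_cohort(scores, responder_rule(horizon_day = 56L))
  resp_w4 <- stats::setNames(st_w4$is_responder, st_w4$patient_id)[patient_id]
  resp_w8 <- stats::setNames(st_w8$is_responder, st_w8$patient_id)[patient_id]

  mis <- config$assessment_misclassification
  draw_assessment <- function(responder, m) {
    out <- character(length(responder))
    for (row in c(TRUE, FALSE)) {
      idx <- which(responder == row)
      if (length(idx)) {
        p <- m[if (row) "responder" else "non_responder", ]
        out[idx] <- .rcat(length(idx), p)
      }
    }
    out
  }
  satisfaction_w4 <- draw_assessment(resp_w4, mis$satisfaction)
  satisfaction_w8 <- draw_assessment(resp_w8, mis$satisfaction)
  investigator_w4 <- draw_assessment(resp_w4, mis$investigator)
  investigator_w8 <- draw_assessment(resp_w8, mis$investigator)

  # HADS follow-up: class-conditional linear decline with noise
  ht <- config$hads_trajectory
  anx_drop <- ifelse(latent_responder, ht$anxiety_drop_w8_responder,
                     ht$anxiety_drop_w8_nonresponder)
  dep_drop <- ifelse(latent_responder, ht$depression_drop_w8_responder,
                     ht$depression_drop_w8_nonresponder)
  clamp_hads <- function(x) as.integer(pmin(21, pmax(0, round(x))))
  hads_anx_w4 <- clamp_hads(hads_anx - anx_drop / 2 +
                              stats::rnorm(n, 0, ht$noise_sd))
  hads_anx_w8 <- clamp_hads(hads_anx - anx_drop +
                              stats::rnorm(n, 0, ht$noise_sd))
  hads_dep_w4 <- clamp_hads(hads_dep - dep_drop / 2 +
                              stats::rnorm(n, 0, ht$noise_sd))
  hads_dep_w8 <- clamp_hads(hads_dep - dep_drop +
                              stats::rnorm(n, 0, ht$noise_sd))

  gz <- config$gerdyzer
  gz_mean <- function(visit) {
    ifelse(latent_responder, gz$mean_responder[[visit]],
           gz$mean_nonresponder[[visit]])
  }
  clamp_vas <- function(x) pmin(100, pmax(0, x))
  gerdyzer_day0 <- clamp_vas(gz_mean("day0") + stats::rnorm(n, 0, gz$noise_sd))
  gerdyzer_w4 <- clamp_vas(gz_mean("w4") + stats::rnorm(n, 0, gz$noise_sd))
  gerdyzer_w8 <- clamp_vas(gz_mean("w8") + stats::rnorm(n, 0, gz$noise_sd))

  patients <- data.frame(
    patient_id = patient_id,
    age = age, bmi = bmi, gender = gender, geography = geography,
    h_pylori = h_pylori, oesophagitis = oesophagitis, ibs_flag = ibs_flag,
    smoking = smoking,
    hads_anxiety_baseline = hads_anx, hads_depression_baseline = hads_dep,
    hads_anxiety_w4 = hads_anx_w4, hads_anxiety_w8 = hads_anx_w8,
    hads_depression_w4 = hads_dep_w4, hads_depression_w8 = hads_dep_w8,
    latent_responder = latent_responder,
    satisfaction_w4 = satisfaction_w4, satisfaction_w8 = satisfaction_w8,
    investigator_w4 = investigator_w4, investigator_w8 = investigator_w8,
    gerdyzer_day0 = gerdyzer_day0, gerdyzer_w4 = gerdyzer_w4,
    gerdyzer_w8 = gerdyzer_w8,
    stringsAsFactors = FALSE
  )
  list(patients = patients, scores = scores)
}

#' Write a cohort to CSV files
#'
#' Emits `patients.csv` (one row per patient) and `daily_scores.csv`
#' (long format: patient_id, day, gi, wso, total) under `dir`.  Numeric
#' columns are written at full double precision so the files round-trip
#' losslessly through [read_cohort()].  Missing values are empty cells.
#'
#' @param patients patient table.
#' @param scores long daily-score table.
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
write_cohort <- function(patients, scores, dir) {
  if (!all(scores$patient_id %in% patients$patient_id)) {
    stop("scores reference unknown patient_id(s): ",
         paste(utils::head(setdiff(scores$patient_id, patients$patient_id), 3),
               collapse = ", "))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    for (col in names(df)) {
      if (is.double(df[[col]])) {
        v <- sprintf("%.17g", df[[col]])
        v[is.na(df[[col]])] <- NA_character_
        df[[col]] <- v
      }
    }
    df
  }
  pp <- file.path(dir, "patients.csv")
  sp <- file.path(dir, "daily_scores.csv")
  utils::write.csv(fmt(patients), pp, row.names = FALSE, na = "")
  utils::write.csv(fmt(scores), sp, row.names = FALSE, na = "")
  invisible(c(patients = pp, scores = sp))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `patients.csv` and `daily_scores.csv`.
#' @return list with `patients` and `scores` tables.
#' @export
read_cohort <- function(dir) {
  pp <- file.path(dir, "patients.csv")
  sp <- file.path(dir, "daily_scores.csv")
  if (!file.exists(pp) || !file.exists(sp)) {
    stop("expected patients.csv and daily_scores.csv under ", dir)
  }
  patients <- utils::read.csv(pp, stringsAsFactors = FALSE, na.strings = "")
  scores <- utils::read.csv(sp, stringsAsFactors = FALSE, na.strings = "")
  if ("latent_responder" %in% names(patients)) {
    patients$latent_responder <- as.logical(patients$latent_responder)
  }
  if (!all(scores$patient_id %in% patients$patient_id)) {
    stop("daily_scores.csv references unknown patient_id(s)")
  }
  list(patients = patients, scores = scores)
}
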