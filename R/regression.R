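# Logistic screening of baseline factors against week-8 responder status.
#
# Factor coding follows the trial's reporting: NERD is the reference for
# ERD/NERD, female for gender, Western Europe for geography, negative for
# H. pylori (intermediate kept as its own level, missing dropped), "no"
# for IBS ("I do not know" kept as a genuine third level).  BMI, age and
# HADS scores enter untransformed.  Complete-case rows only; the dropped
# count is reported.  P-values are Wald and interpreted exploratively (no
# multiplicity adjustment, mirroring the analysis being reproduced).

#' Factor specifications for the response-factor screen
#'
#' @return data.frame naming each screened factor, its kind and, for
#'   categorical factors, the reference level.
#' @export
factor_specs <- function() {
  data.frame(
    name = c("erd_nerd", "hads_total", "hads_anxiety", "hads_depression",
             "ibs", "bmi", "gender", "geography", "h_pylori", "age",
             "oesophagitis_grade"),
    kind = c("binary", "continuous", "continuous", "continuous",
             "categorical", "continuous", "binary", "categorical",
             "categorical", "continuous", "categorical"),
    reference = c("NERD", NA, NA, NA, "no", NA, "female", "Western Europe",
                  "negative", NA, "A"),
    stringsAsFactors = FALSE
  )
}

# Derive analysis variables from the patient table; returns a data.frame
# with one column per screenable factor plus patient_id.
.analysis_frame <- function(cohort) {
  oe <- cohort$oesophagitis
  erd <- ifelse(oe %in% c("A", "B", "C", "D"), "ERD",
                ifelse(oe == "NERD", "NERD", NA))
  hp <- ifelse(cohort$h_pylori == "missing", NA, cohort$h_pylori)
  data.frame(
    patient_id = cohort$patient_id,
    erd_nerd = factor(erd, levels = c("NERD", "ERD")),
    hads_total = cohort$hads_anxiety_baseline + cohort$hads_depression_baseline,
    hads_anxiety = cohort$hads_anxiety_baseline,
    hads_depression = cohort$hads_depression_baseline,
    ibs = factor(cohort$ibs_flag, levels = c("no", "yes", "unknown")),
    bmi = cohort$bmi,
    gender = factor(cohort$gender, levels = c("female", "male")),
    geography = factor(cohort$geography,
                       levels = c("Western Europe", "South America", "Asia",
                                  "Canada", "South Africa", "Australia")),
    h_pylori = factor(hp, levels = c("negative", "positive", "intermediate")),
    age = cohort$age,
    oesophagitis_grade = factor(ifelse(oe %in% c("A", "B", "C", "D"), oe, NA),
                                levels = c("A", "B", "C", "D")),
    stringsAsFactors = FALSE
  )
}

#' Encode screened factors into a complete-case design frame
#'
#' Builds the analysis variables (ERD/NERD indicator, HADS totals and
#' sub-scores, IBS, BMI, gender, geography, H. pylori, age, oesophagitis
#' grade) from a patient table, drops rows with a missing required field
#' and reports the count, and flags degenerate columns (a factor observed
#' at fewer than two levels, or a constant continuous factor).
#'
#' @param cohort patient table from [generate_cohort()] / [read_cohort()].
#' @param factors character vector of factor names (see [factor_specs()]).
#' @return list with `data` (complete-case frame incl. `patient_id`),
#'   `factors`, `n_used`, `n_dropped`, `degenerate` (character vector).
#' @export
encode_factors <- function(cohort, factors) {
  specs <- factor_specs()
  unknown <- setdiff(factors, specs$name)
  if (length(unknown)) {
    stop("unknown factor(s): ", paste(unknown, collapse = ", "))
  }
  af <- .analysis_frame(cohort)
  keep <- af[, c("patient_id", factors), drop = FALSE]
  cc <- stats::complete.cases(keep[, factors, drop = FALSE])
  used <- keep[cc, , drop = FALSE]
  degen <- character(0)
  for (f in factors) {
    v <- used[[f]]
    if (is.factor(v)) {
      v <- droplevels(v)
      if (nlevels(v) < 2) degen <- c(degen, f)
      used[[f]] <- v
    } else if (length(unique(v)) < 2) {
      degen <- c(degen, f)
    }
  }
  list(data = used, factors = factors,
       n_used = nrow(used), n_dropped = sum(!cc), degenerate = degen)
}

#' Fit a logistic regression of a binary outcome on encoded factors
#'
#' Maximum likelihood via iteratively reweighted least squares
#' (`stats::glm`, binomial logit, deviance tolerance 1e-10) with Wald
#' standard errors.  Non-convergence and (quasi-)complete separation are
#' flagged on the result instead of being reported as ordinary estimates.
#'
#' @param design result of [encode_factors()].
#' @param outcome logical/0-1 vector aligned with `design$data` rows.
#' @param model_label label copied into the coefficient table.
#' @return list of class `logistic_fit`: `coefficients` (data.frame with
#'   term, estimate, se, odds_ratio, p), `n_used`, `converged`,
#'   `separation`, `model`.
#' @export
fit_logistic <- function(design, outcome, model_label = "model") {
  if (length(design$factors) == 0) stop("no factors supplied")
  if (length(outcome) != nrow(design$data)) {
    stop("outcome length must match the design rows")
  }
  if (any(is.na(outcome))) stop("outcome must be non-missing")
  y <- as.numeric(outcome)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary")
  if (length(design$degenerate)) {
    stop("degenerate factor(s) in design: ",
         paste(design$degenerate, collapse = ", "))
  }
  if (nrow(design$data) < 2 || length(unique(y)) < 2) {
    stop("outcome must vary: need both responders and non-responders")
  }
  df <- design$data
  df$.y <- y
  fml <- stats::as.formula(paste(".y ~", paste(design$factors, collapse = " + ")))
  fit <- stats::glm(fml, family = stats::binomial(), data = df,
                    control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  sm <- summary(fit)$coefficients
  mu <- stats::fitted(fit)
  separation <- any(mu > 1 - 1e-8 | mu < 1e-8) || any(abs(stats::coef(fit)) > 15)
  coefs <- data.frame(
    model = model_label,
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    se = sm[, "Std. Error"],
    odds_ratio = exp(sm[, "Estimate"]),
    p = sm[, "Pr(>|z|)"],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  structure(
    list(coefficients = coefs, n_used = nrow(df),
         n_dropped = design$n_dropped,
         converged = fit$converged, separation = separation,
         model = model_label, glm = fit),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit '%s' (n = %d%s)%s%s\n", x$model, x$n_used,
              if (x$n_dropped > 0) sprintf(", %d dropped", x$n_dropped) else "",
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (x$separation) " [SEPARATION]" else ""))
  print(x$coefficients[, c("term", "estimate", "se", "odds_ratio", "p")],
        digits = 4, row.names = FALSE)
  invisible(x)
}

# Join responder flags onto the analysis rows for a factor set.
.design_with_outcome <- function(cohort, statuses, factors, subset_ids = NULL) {
  design <- encode_factors(cohort, factors)
  if (!is.null(subset_ids)) {
    design$data <- design$data[design$data$patient_id %in% subset_ids, ,
                               drop = FALSE]
    design$n_used <- nrow(design$data)
    for (f in design$factors) {
      if (is.factor(design$data[[f]])) {
        design$data[[f]] <- droplevels(design$data[[f]])
        if (nlevels(design$data[[f]]) < 2) {
          design$degenerate <- union(design$degenerate, f)
        }
      }
    }
  }
  flag <- stats::setNames(statuses$is_responder,
                          as.character(statuses$patient_id))
  y <- flag[as.character(design$data$patient_id)]
  if (any(is.na(y))) stop("responder status missing for some patients")
  list(design = design, outcome = as.logical(y))
}

#' Univariate screen of every response factor
#'
#' One single-factor logistic fit per screened factor, with week-8
#' responder status as the outcome.  Oesophagitis grade (A-D) is fitted
#' within the ERD subgroup only, since the grade is undefined for NERD.
#'
#' @param cohort patient table.
#' @param statuses week-8 responder statuses ([classify_cohort()]).
#' @param factors factors to screen; defaults to the full set.
#' @return named list of `logistic_fit` objects.
#' @export
univariate_screen <- function(cohort, statuses,
                              factors = factor_specs()$name) {
  if (nrow(cohort) < 2) stop("need at least 2 patients")
  fits <- list()
  for (f in factors) {
    subset_ids <- NULL
    if (f == "oesophagitis_grade") {
      subset_ids <- cohort$patient_id[cohort$oesophagitis %in%
                                        c("A", "B", "C", "D")]
    }
    dw <- .design_with_outcome(cohort, statuses, f, subset_ids)
    fits[[f]] <- fit_logistic(dw$design, dw$outcome, model_label = f)
  }
  fits
}

#' Global multivariate model of response
#'
#' One joint logistic model with ERD/NERD, HADS total score, IBS, BMI,
#' gender, geography, H. pylori and age.  Oesophagitis grades and the
#' HADS sub-scores are excluded: ERD/NERD enters only by presence and
#' HADS only as the total.
#'
#' @inheritParams univariate_screen
#' @return a `logistic_fit`.
#' @export
multivariate_fit <- function(cohort, statuses) {
  factors <- c("erd_nerd", "hads_total", "ibs", "bmi", "gender",
               "geography", "h_pylori", "age")
  dw <- .design_with_outcome(cohort, statuses, factors)
  fit_logistic(dw$design, dw$outcome, model_label = "multivariate")
}

#' Flatten a list of fits into one results table
#'
#' @param fits list of `logistic_fit` objects.
#' @return data.frame (model, term, estimate, se, odds_ratio, p, n_used,
#'   converged, separation).
#' @export
regression_table <- function(fits) {
  if (inherits(fits, "logistic_fit")) fits <- list(fits)
  do.call(rbind, lapply(fits, function(f) {
    cbind(f$coefficients, n_used = f$n_used, converged = f$converged,
          separation = f$separation)
  }))
}
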