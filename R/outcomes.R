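# Concordance of score-defined response with patient satisfaction and
# investigator assessment, and quality-of-life (GERDyzer) summaries.

SATISFACTION_LEVELS <- c("very", "fairly", "not")
INVESTIGATOR_LEVELS <- c("well", "fairly", "not")

#' Cross-tabulate an assessment against responder status
#'
#' Builds the 3 x 2 table of assessment category (very/fairly/not
#' satisfied, or well/fairly/not controlled) against responder status at
#' the matching visit.  Patients without the assessment are excluded and
#' counted.
#'
#' @param cohort patient table.
#' @param statuses responder statuses at the visit horizon (day 28 for
#'   week4, day 56 for week8).
#' @param assessment_kind `"satisfaction"` or `"investigator"`.
#' @param visit `"week4"` or `"week8"`.
#' @return list of class `concordance_table`: `counts` (3 x 2 matrix,
#'   categories x responder status), `proportions` (row-wise),
#'   `n_assessed`, `n_missing`, plus the kind/visit labels.
#' @export
crosstab_assessment <- function(cohort, statuses,
                                assessment_kind = c("satisfaction",
                                                    "investigator"),
                                visit = c("week8", "week4")) {
  assessment_kind <- match.arg(assessment_kind)
  visit <- match.arg(visit)
  col <- paste0(assessment_kind, "_", sub("week", "w", visit))
  if (!col %in% names(cohort)) stop("cohort lacks column ", col)
  levs <- if (assessment_kind == "satisfaction") SATISFACTION_LEVELS
          else INVESTIGATOR_LEVELS
  flag <- stats::setNames(statuses$is_responder,
                          as.character(statuses$patient_id))
  resp <- flag[as.character(cohort$patient_id)]
  if (any(is.na(resp))) stop("responder status missing for some patients")
  cat_ <- cohort[[col]]
  present <- !is.na(cat_) & cat_ != ""
  bad <- present & !(cat_ %in% levs)
  if (any(bad)) {
    stop("unknown ", assessment_kind, " category: ",
         paste(unique(cat_[bad]), collapse = ", "))
  }
  counts <- table(factor(cat_[present], levels = levs),
                  factor(ifelse(resp[present], "responder", "non_responder"),
                         levels = c("responder", "non_responder")))
  counts <- unclass(counts)
  structure(
    list(assessment_kind = assessment_kind, visit = visit,
         counts = counts,
         proportions = sweep(counts, 1, pmax(rowSums(counts), 1), "/"),
         n_assessed = sum(present), n_missing = sum(!present)),
    class = "concordance_table"
  )
}

#' @export
print.concordance_table <- function(x, ...) {
  cat(sprintf("%s x responder status at %s (n = %d assessed, %d missing)\n",
              x$assessment_kind, x$visit, x$n_assessed, x$n_missing))
  print(x$counts)
  invisible(x)
}

#' Discordance proportions from a concordance table
#'
#' Reports the two headline discordance measures: the non-responder share
#' inside the top assessment category ("very satisfied" / "well
#' controlled"), and the share of responders who nevertheless fell in the
#' bottom category ("not satisfied" / "not controlled").  A proportion
#' with a zero denominator is returned as `NA` and flagged.
#'
#' @param table a [crosstab_assessment()] result.
#' @return list with `top_category_nonresponder_share`,
#'   `responders_in_bottom_category_share`, the corresponding counts, and
#'   `undefined` naming any measure with an empty denominator.
#' @export
discordance_summary <- function(table) {
  if (!inherits(table, "concordance_table")) {
    stop("table must come from crosstab_assessment()")
  }
  counts <- table$counts
  top <- rownames(counts)[1]     # "very" / "well"
  bottom <- rownames(counts)[3]  # "not"
  n_top <- sum(counts[top, ])
  n_resp <- sum(counts[, "responder"])
  undefined <- character(0)
  a <- if (n_top > 0) counts[top, "non_responder"] / n_top else {
    undefined <- c(undefined, "top_category_nonresponder_share"); NA_real_
  }
  b <- if (n_resp > 0) counts[bottom, "responder"] / n_resp else {
    undefined <- c(undefined, "responders_in_bottom_category_share"); NA_real_
  }
  list(
    assessment_kind = table$assessment_kind,
    visit = table$visit,
    top_category_nonresponder_share = a,
    top_category_n = as.integer(n_top),
    top_category_nonresponders = as.integer(counts[top, "non_responder"]),
    responders_in_bottom_category_share = b,
    responders_n = as.integer(n_resp),
    responders_in_bottom_category = as.integer(counts[bottom, "responder"]),
    undefined = undefined
  )
}

#' Quality-of-life summary by responder group
#'
#' GERDyzer group means at baseline, week 4 and week 8, baseline-to-visit
#' changes per group, and an unpaired large-sample (Welch) comparison of
#' the changes between responders and non-responders.
#'
#' @param cohort patient table with `gerdyzer_day0/w4/w8`.
#' @param statuses week-8 responder statuses.
#' @return list with `means` (group x visit data.frame), `changes`
#'   (group x visit), and `tests` (per-visit z statistic and p-value for
#'   the responder/non-responder difference in change).
#' @export
qol_summary <- function(cohort, statuses) {
  flag <- stats::setNames(statuses$is_responder,
                          as.character(statuses$patient_id))
  resp <- flag[as.character(cohort$patient_id)]
  if (any(is.na(resp))) stop("responder status missing for some patients")
  groups <- split(cohort, ifelse(resp, "responder", "non_responder"))
  if (length(groups) < 2) {
    warning("one responder group is empty; no between-group test")
  }
  visits <- c(day0 = "gerdyzer_day0", week4 = "gerdyzer_w4",
              week8 = "gerdyzer_w8")
  means <- do.call(rbind, lapply(names(groups), function(g) {
    data.frame(group = g, n = nrow(groups[[g]]),
               t(vapply(visits, function(v) mean(groups[[g]][[v]]),
                        numeric(1))))
  }))
  changes <- do.call(rbind, lapply(names(groups), function(g) {
    d <- groups[[g]]
    data.frame(group = g,
               week4 = mean(d$gerdyzer_w4 - d$gerdyzer_day0),
               week8 = mean(d$gerdyzer_w8 - d$gerdyzer_day0))
  }))
  tests <- NULL
  if (all(c("responder", "non_responder") %in% names(groups)) &&
      nrow(groups$responder) > 1 && nrow(groups$non_responder) > 1) {
    tests <- do.call(rbind, lapply(c("week4", "week8"), function(v) {
      col <- visits[[v]]
      dr <- groups$responder[[col]] - groups$responder$gerdyzer_day0
      dn <- groups$non_responder[[col]] - groups$non_responder$gerdyzer_day0
      diff <- mean(dr) - mean(dn)
      se <- sqrt(stats::var(dr) / length(dr) + stats::var(dn) / length(dn))
      z <- if (se > 0) diff / se else if (diff == 0) 0 else sign(diff) * Inf
      data.frame(visit = v, diff_in_change = diff,
                 statistic = z, p = 2 * stats::pnorm(-abs(z)))
    }))
  }
  list(means = means, changes = changes, tests = tests)
}
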