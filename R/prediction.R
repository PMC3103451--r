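# Dual prediction-level (grey-zone) search over early-treatment scores.
#
# For a candidate day and score kind, every level L on a 0.01-step grid
# from 0 to the score maximum splits patients into a predicted-response
# group (score <= L) and a predicted-non-response group (score > L).  The
# response prediction rate is the observed week-8 responder proportion in
# the low group; the non-response prediction rate the non-responder
# proportion in the high group.  The optimal day minimises the width of
# the indeterminate zone between the two chosen levels.

SCORE_MAXIMA <- c(gi = 30.77, wso = 15.51, total = 46.28)

#' Prediction rates at a single level
#'
#' @param day_scores named numeric vector (names = patient ids) of scores
#'   on one day; patients with a missing score should be omitted/NA.
#' @param responder_flags named logical vector of week-8 responder status,
#'   covering every scored patient.
#' @param level cutoff; predicted response = score <= level.
#' @return list with `response_rate`, `nonresponse_rate` (NA when the
#'   corresponding group is empty), `n_low`, `n_high`, `n_resp_low`,
#'   `n_nonresp_high`.
#' @export
prediction_rates_at_level <- function(day_scores, responder_flags, level) {
  if (length(day_scores) == 0) stop("day_scores is empty")
  if (level < 0) stop("level must be >= 0")
  keep <- !is.na(day_scores)
  day_scores <- day_scores[keep]
  if (length(day_scores) == 0) stop("no present scores")
  flags <- responder_flags[names(day_scores)]
  if (any(is.na(flags))) {
    stop("responder_flags must be defined for every scored patient")
  }
  low <- day_scores <= level
  n_low <- sum(low); n_high <- sum(!low)
  n_resp_low <- sum(flags[low])
  n_nonresp_high <- sum(!flags[!low])
  list(
    response_rate = if (n_low > 0) n_resp_low / n_low else NA_real_,
    nonresponse_rate = if (n_high > 0) n_nonresp_high / n_high else NA_real_,
    n_low = n_low, n_high = n_high,
    n_resp_low = n_resp_low, n_nonresp_high = n_nonresp_high
  )
}

#' Sweep the full level grid for one day
#'
#' Levels run from 0 to `score_max` in steps of `step` (grid arithmetic
#' uses integer level indices, level = k * step, to keep boundaries
#' stable).  Patients with a missing score that day are excluded from the
#' denominators.
#'
#' @param day_scores named numeric vector of scores on the candidate day.
#' @param responder_flags named logical week-8 responder flags.
#' @param step grid step (default 0.01).
#' @param score_max top of the grid (e.g. 30.77 for GI).
#' @return data.frame of class `level_sweep` with one row per level:
#'   `level`, `n_low`, `n_resp_low`, `response_rate`, `n_high`,
#'   `n_nonresp_high`, `nonresponse_rate`.
#' @export
sweep_day <- function(day_scores, responder_flags, step = 0.01,
                      score_max = max(day_scores, na.rm = TRUE)) {
  if (!is.numeric(step) || length(step) != 1 || step <= 0) {
    stop("step must be a single positive number")
  }
  keep <- !is.na(day_scores)
  day_scores <- day_scores[keep]
  if (length(day_scores) == 0) stop("day_scores has no present scores")
  flags <- responder_flags[names(day_scores)]
  if (any(is.na(flags))) {
    stop("responder_flags must cover every scored patient")
  }
  k <- 0:floor(score_max / step + 1e-9)
  levels <- k * step
  tol <- step * 1e-6  # absorb representation error at grid boundaries
  n <- length(day_scores)
  sorted_all <- sort(day_scores)
  sorted_resp <- sort(day_scores[flags])
  n_resp <- length(sorted_resp)
  n_low <- findInterval(levels + tol, sorted_all)
  n_resp_low <- findInterval(levels + tol, sorted_resp)
  n_high <- n - n_low
  n_nonresp_high <- (n - n_resp) - (n_low - n_resp_low)
  out <- data.frame(
    level = levels,
    n_low = n_low,
    n_resp_low = n_resp_low,
    response_rate = ifelse(n_low > 0, n_resp_low / n_low, NA_real_),
    n_high = n_high,
    n_nonresp_high = n_nonresp_high,
    nonresponse_rate = ifelse(n_high > 0, n_nonresp_high / n_high, NA_real_)
  )
  attr(out, "n_patients") <- n
  attr(out, "step") <- step
  class(out) <- c("level_sweep", "data.frame")
  out
}

#' Choose the two prediction levels for one day
#'
#' The response level L is the largest grid level attaining the maximal
#' response prediction rate among levels whose predicted-response group
#' has at least `min_group` patients (largest L maximises coverage); the
#' non-response level U is the smallest level attaining the maximal
#' non-response rate among levels with at least `min_group` patients above
#' them.  A day with L > U, or with no level meeting `min_group` on either
#' side, is flagged inadmissible rather than erroring.
#'
#' @param sweep a [sweep_day()] result.
#' @param min_group minimum patients in a predicted group for a level to
#'   be eligible (default 30; without a support floor a single-patient
#'   group trivially attains rate 1).
#' @param day,score_kind optional labels carried into the result.
#' @return list of class `day_prediction` with `response_level`,
#'   `nonresponse_level`, the two rates and group sizes,
#'   `indeterminate_width` and `admissible`.
#' @export
optimize_day <- function(sweep, min_group = 30L, day = NA_integer_,
                         score_kind = NA_character_) {
  if (!inherits(sweep, "level_sweep") || nrow(sweep) == 0) {
    stop("sweep must be a nonempty level_sweep")
  }
  res <- list(day = day, score_kind = score_kind,
              response_level = NA_real_, nonresponse_level = NA_real_,
              response_rate = NA_real_, nonresponse_rate = NA_real_,
              n_low = NA_integer_, n_high = NA_integer_,
              indeterminate_width = NA_real_, admissible = FALSE,
              min_group = as.integer(min_group))
  class(res) <- "day_prediction"

  lo_ok <- which(sweep$n_low >= min_group)
  hi_ok <- which(sweep$n_high >= min_group)
  if (length(lo_ok) == 0 || length(hi_ok) == 0) return(res)

  r <- sweep$response_rate[lo_ok]
  best_r <- max(r)
  iL <- lo_ok[max(which(r == best_r))]           # largest qualifying level
  nr <- sweep$nonresponse_rate[hi_ok]
  best_nr <- max(nr)
  iU <- hi_ok[min(which(nr == best_nr))]         # smallest qualifying level

  res$response_level <- sweep$level[iL]
  res$nonresponse_level <- sweep$level[iU]
  res$response_rate <- sweep$response_rate[iL]
  res$nonresponse_rate <- sweep$nonresponse_rate[iU]
  res$n_low <- sweep$n_low[iL]
  res$n_high <- sweep$n_high[iU]
  res$indeterminate_width <- res$nonresponse_level - res$response_level
  res$admissible <- res$response_level <= res$nonresponse_level
  res
}

#' @export
print.day_prediction <- function(x, ...) {
  cat(sprintf(
    "Day %s (%s): response <= %.2f (n=%s, rate %.1f%%); non-response > %.2f (n=%s, rate %.1f%%); width %.2f%s\n",
    x$day, x$score_kind, x$response_level, x$n_low, 100 * x$response_rate,
    x$nonresponse_level, x$n_high, 100 * x$nonresponse_rate,
    x$indeterminate_width, if (x$admissible) "" else " [inadmissible]"))
  invisible(x)
}

#' Select the best prediction day for each score kind
#'
#' Runs the level sweep for each candidate day and score kind, picks the
#' per-day optimal levels, and selects as "best" the admissible treatment
#' day (1-10) minimising the indeterminate-zone width, ties going to the
#' earliest day.  Day 0 (pre-treatment) is reported separately as the
#' baseline prediction.
#'
#' @param scores long daily-score table (`patient_id`, `day`, `gi`,
#'   `wso`, `total`).
#' @param statuses responder statuses at the week-8 horizon
#'   ([classify_cohort()] output).
#' @param score_kinds subset of `c("gi","wso","total")`.
#' @param days candidate treatment days (default 1:10).
#' @param step grid step (default 0.01).
#' @param min_group support floor per predicted group (default 30).
#' @return list of class `prediction_summary`: `per_day` (data.frame of
#'   every day/kind result), `best` and `baseline` (one row per kind).
#' @export
select_best_day <- function(scores, statuses,
                            score_kinds = c("gi", "wso", "total"),
                            days = 1:10, step = 0.01, min_group = 30L) {
  stopifnot(all(score_kinds %in% names(SCORE_MAXIMA)))
  flags <- stats::setNames(statuses$is_responder,
                           as.character(statuses$patient_id))
  rows <- list()
  for (kind in score_kinds) {
    for (d in sort(unique(c(0L, days)))) {
      sub <- scores[scores$day == d, ]
      sc <- stats::setNames(sub[[kind]], as.character(sub$patient_id))
      sc <- sc[!is.na(sc)]
      sc <- sc[names(sc) %in% names(flags)]
      if (length(sc) == 0) next
      sw <- sweep_day(sc, flags, step = step,
                      score_max = SCORE_MAXIMA[[kind]])
      opt <- optimize_day(sw, min_group = min_group, day = d,
                          score_kind = kind)
      rows[[length(rows) + 1L]] <- as.data.frame(
        opt[c("day", "score_kind", "response_level", "nonresponse_level",
              "response_rate", "nonresponse_rate", "n_low", "n_high",
              "indeterminate_width", "admissible")])
    }
  }
  per_day <- do.call(rbind, rows)
  best <- baseline <- per_day[0, ]
  for (kind in score_kinds) {
    kd <- per_day[per_day$score_kind == kind, ]
    baseline <- rbind(baseline, kd[kd$day == 0L, ])
    cand <- kd[kd$day %in% days & kd$admissible, ]
    if (nrow(cand) > 0) {
      cand <- cand[order(cand$indeterminate_width, cand$day), ]
      best <- rbind(best, cand[1, ])
    }
  }
  structure(list(per_day = per_day, best = best, baseline = baseline,
                 step = step, min_group = as.integer(min_group)),
            class = "prediction_summary")
}

#' @export
print.prediction_summary <- function(x, ...) {
  cat("Best prediction day per score kind (days 1-10):\n")
  print(format_prediction_table(x$best), row.names = FALSE)
  cat("\nBaseline (day 0) prediction:\n")
  print(format_prediction_table(x$baseline), row.names = FALSE)
  invisible(x)
}

#' Format a prediction table with percentage rates
#'
#' Percentages are 100 x rate rounded to one decimal.
#'
#' @param tab rows of a `prediction_summary` component.
#' @return data.frame with human-readable columns.
#' @export
format_prediction_table <- function(tab) {
  data.frame(
    score = tab$score_kind,
    day = tab$day,
    response_level = tab$response_level,
    n_response = tab$n_low,
    response_rate_pct = round(100 * tab$response_rate, 1),
    nonresponse_level = tab$nonresponse_level,
    n_nonresponse = tab$n_high,
    nonresponse_rate_pct = round(100 * tab$nonresponse_rate, 1),
    width = tab$indeterminate_width
  )
}
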