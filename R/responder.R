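# Responder classification from daily ReQuest-GI scores.
#
# A patient responds when the daily GI score stays below 1.6 on a run of
# 3 consecutive calendar days inside the treatment window; 1.6 is the 95%
# upper confidence limit of GI scores in healthy subjects.  Day 0 is the
# pre-treatment day and never counts towards a run; a missing day breaks
# a run.

#' Responder classification rule
#'
#' @param threshold score threshold; default 1.6 (upper 95% confidence
#'   limit of the GI score in healthy subjects).
#' @param run_length number of consecutive qualifying days required
#'   (default 3).
#' @param strict if `TRUE` (default) a day qualifies when score <
#'   threshold; if `FALSE`, score <= threshold.
#' @param window_start_day first day a run may occupy; default 1 (day 0 is
#'   pre-treatment).
#' @param horizon_day last day a run may end: 28 for Week 4, 56 for Week 8.
#' @param skip_missing if `TRUE`, missing days are skipped rather than
#'   breaking a run; default `FALSE` (conservative).
#' @return object of class `responder_rule`.
#' @export
responder_rule <- function(threshold = 1.6, run_length = 3L, strict = TRUE,
                           window_start_day = 1L, horizon_day = 56L,
                           skip_missing = FALSE) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    stop("threshold must be a single positive number")
  }
  run_length <- as.integer(run_length)
  if (is.na(run_length) || run_length < 1L) stop("run_length must be >= 1")
  window_start_day <- as.integer(window_start_day)
  horizon_day <- as.integer(horizon_day)
  if (window_start_day > horizon_day) {
    stop("window_start_day must not exceed horizon_day")
  }
  structure(
    list(threshold = threshold, run_length = run_length, strict = strict,
         window_start_day = window_start_day, horizon_day = horizon_day,
         skip_missing = skip_missing),
    class = "responder_rule"
  )
}

#' @export
print.responder_rule <- function(x, ...) {
  cat(sprintf(
    "Responder rule: GI score %s %.2f on %d consecutive days, days %d-%d%s\n",
    if (x$strict) "<" else "<=", x$threshold, x$run_length,
    x$window_start_day, x$horizon_day,
    if (x$skip_missing) " (missing days skipped)" else ""))
  invisible(x)
}

# Core scan for one patient: days/scores vectors -> end day of the first
# qualifying run, or NA.  Runs must be consecutive *calendar* days, so a
# missing day breaks a run unless the rule skips missing days.
.first_qualifying_run <- function(day, score, rule) {
  keep <- day >= rule$window_start_day & day <= rule$horizon_day
  day <- day[keep]; score <- score[keep]
  if (rule$skip_missing) {
    keep <- !is.na(score)
    day <- day[keep]; score <- score[keep]
    if (length(day) < rule$run_length) return(NA_integer_)
    ok <- if (rule$strict) score < rule$threshold else score <= rule$threshold
    run <- 0L
    for (i in seq_along(day)) {
      run <- if (ok[i]) run + 1L else 0L
      if (run >= rule$run_length) return(as.integer(day[i]))
    }
    return(NA_integer_)
  }
  # calendar-day grid: absent days are non-qualifying
  grid_days <- rule$window_start_day:rule$horizon_day
  sc <- rep(NA_real_, length(grid_days))
  sc[match(day, grid_days)] <- score
  ok <- !is.na(sc) & (if (rule$strict) sc < rule$threshold else sc <= rule$threshold)
  run <- 0L
  for (i in seq_along(grid_days)) {
    run <- if (ok[i]) run + 1L else 0L
    if (run >= rule$run_length) return(grid_days[i])
  }
  NA_integer_
}

#' Classify one patient's daily score series
#'
#' @param series data.frame with columns `day` and `gi` (or the score
#'   column named by `score_col`) for one patient; days in 0..56, missing
#'   scores as `NA` or absent rows.
#' @param rule a [responder_rule()].
#' @param score_col name of the score column to classify on; default
#'   `"gi"` (the responder definition uses the GI sub-scale).
#' @return list with `is_responder`, `first_qualifying_run_end_day`
#'   (`NA` if none) and `horizon_day`.
#' @export
classify_responder <- function(series, rule = responder_rule(),
                               score_col = "gi") {
  if (!is.data.frame(series) || nrow(series) == 0) {
    stop("series must be a nonempty data.frame of daily scores")
  }
  if (!all(c("day", score_col) %in% names(series))) {
    stop("series needs columns 'day' and '", score_col, "'")
  }
  if (any(series$day < 0 | series$day > 56)) {
    stop("days must lie in [0, 56]")
  }
  if (anyDuplicated(series$day)) stop("duplicate days in series")
  end_day <- .first_qualifying_run(series$day, series[[score_col]], rule)
  list(
    is_responder = !is.na(end_day),
    first_qualifying_run_end_day = end_day,
    horizon_day = rule$horizon_day
  )
}

#' Classify every patient in a long-format daily-score table
#'
#' Vectorised over patients: computes, for each patient, whether a run of
#' `run_length` consecutive present days with qualifying scores ends on or
#' before the horizon.
#'
#' @param scores long data.frame (`patient_id`, `day`, `gi`, ...).
#' @param rule a [responder_rule()].
#' @param score_col score column used by the rule (default `"gi"`).
#' @return data.frame (`patient_id`, `horizon_day`, `is_responder`,
#'   `run_end_day`), one row per patient.
#' @export
classify_cohort <- function(scores, rule = responder_rule(),
                            score_col = "gi") {
  if (!is.data.frame(scores) || nrow(scores) == 0) {
    stop("scores must be a nonempty long-format data.frame")
  }
  if (!all(c("patient_id", "day", score_col) %in% names(scores))) {
    stop("scores needs columns patient_id, day, ", score_col)
  }
  ids <- unique(scores$patient_id)
  # wide day-by-patient matrix over the rule window for a vectorised scan
  days <- rule$window_start_day:rule$horizon_day
  sub <- scores[scores$day %in% days, c("patient_id", "day", score_col)]
  m <- matrix(NA_real_, nrow = length(days), ncol = length(ids),
              dimnames = list(NULL, as.character(ids)))
  m[cbind(match(sub$day, days), match(sub$patient_id, ids))] <- sub[[score_col]]
  ok <- !is.na(m) & (if (rule$strict) m < rule$threshold else m <= rule$threshold)
  if (rule$skip_missing) {
    # collapse missing days out of each column before run detection
    run_end <- vapply(seq_along(ids), function(j) {
      keep <- !is.na(m[, j])
      .run_end_from_ok(ok[keep, j], days[keep], rule$run_length)
    }, integer(1))
  } else {
    storage.mode(ok) <- "integer"
    run <- ok
    if (nrow(ok) >= 2) {
      for (i in 2:nrow(ok)) {
        run[i, ] <- ifelse(ok[i, ] == 1L, run[i - 1L, ] + 1L, 0L)
      }
    }
    hit <- run >= rule$run_length
    first_row <- apply(hit, 2, function(col) {
      w <- which(col)
      if (length(w)) w[1] else NA_integer_
    })
    run_end <- ifelse(is.na(first_row), NA_integer_, days[first_row])
  }
  data.frame(
    patient_id = ids,
    horizon_day = rule$horizon_day,
    is_responder = !is.na(run_end),
    run_end_day = as.integer(run_end),
    stringsAsFactors = FALSE
  )
}

.run_end_from_ok <- function(ok, days, run_length) {
  run <- 0L
  for (i in seq_along(ok)) {
    run <- if (isTRUE(ok[i])) run + 1L else 0L
    if (run >= run_length) return(as.integer(days[i]))
  }
  NA_integer_
}

#' Cohort response rate
#'
#' @param statuses data.frame from [classify_cohort()] (or any table with
#'   logical `is_responder` and a single shared `horizon_day`).
#' @return proportion of responders in [0, 1].
#' @export
cohort_response_rate <- function(statuses) {
  if (!is.data.frame(statuses) || nrow(statuses) == 0) {
    stop("statuses must be a nonempty data.frame")
  }
  if (!"is_responder" %in% names(statuses)) {
    stop("statuses needs an is_responder column")
  }
  if ("horizon_day" %in% names(statuses) &&
      length(unique(statuses$horizon_day)) != 1) {
    stop("all statuses must share one horizon")
  }
  mean(statuses$is_responder)
}
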