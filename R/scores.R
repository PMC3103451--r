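# Instrument scoring: ReQuest short form, HADS, GERDyzer.

# ReQuest dimension names and the sub-scale each belongs to.  The GI
# sub-scale spans 0-30.77, WSO 0-15.51, the total 0-46.28.
REQUEST_GI_DIMS <- c("acid", "upper_abdominal", "lower_abdominal", "nausea")
REQUEST_WSO_DIMS <- c("wellbeing", "sleep", "other")
REQUEST_GI_MAX <- 30.77
REQUEST_WSO_MAX <- 15.51
REQUEST_TOTAL_MAX <- REQUEST_GI_MAX + REQUEST_WSO_MAX

#' Default per-dimension ReQuest weights
#'
#' The proprietary item-to-score algorithm for the ReQuest short form is
#' not public; this package uses a documented stand-in in which each
#' sub-scale maximum is split equally across its dimensions, so the
#' attainable sub-scale ranges (GI 0-30.77, WSO 0-15.51, total 0-46.28)
#' are preserved exactly.
#'
#' @return Named numeric vector of per-dimension maxima, one entry per
#'   ReQuest dimension, summing to 46.28.
#' @export
request_default_weights <- function() {
  w <- c(
    stats::setNames(rep(REQUEST_GI_MAX / 4, 4), REQUEST_GI_DIMS),
    stats::setNames(rep(REQUEST_WSO_MAX / 3, 3), REQUEST_WSO_DIMS)
  )
  w
}

#' Score one day of ReQuest item responses
#'
#' Aggregates the seven ReQuest dimensions (acid, upper abdominal, lower
#' abdominal, nausea, sleep, other complaints, general well-being) into
#' the GI and WSO sub-scales and the total score.  Intensity is a 0-100 mm
#' VAS; frequency a 7-point (0-6) Likert item, absent for the well-being
#' dimension which is VAS-only.  The default rule is multiplicative:
#' dimension score = weight * (intensity/100) * (frequency/6), and
#' weight * (intensity/100) for well-being.
#'
#' @param items data.frame with columns `dimension`, `intensity` and
#'   `frequency` (`frequency` must be `NA` exactly for the well-being row);
#'   exactly one row per dimension.
#' @param weights named numeric vector of per-dimension maxima; defaults to
#'   an equal split of each sub-scale maximum (see
#'   [request_default_weights()]).
#' @return A one-row data.frame with per-dimension scores plus `gi`, `wso`
#'   and `total`.
#' @export
score_request_day <- function(items, weights = request_default_weights()) {
  stopifnot(is.data.frame(items))
  need <- c("dimension", "intensity", "frequency")
  if (!all(need %in% names(items))) {
    stop("items must have columns dimension, intensity, frequency")
  }
  all_dims <- c(REQUEST_GI_DIMS, REQUEST_WSO_DIMS)
  if (!setequal(items$dimension, all_dims) || nrow(items) != length(all_dims)) {
    stop("exactly one response per ReQuest dimension is required; got: ",
         paste(items$dimension, collapse = ", "))
  }
  if (!setequal(names(weights), all_dims)) {
    stop("weights must be named by the seven ReQuest dimensions")
  }
  if (any(weights < 0)) stop("weights must be nonnegative")
  items <- items[match(all_dims, items$dimension), ]
  if (any(is.na(items$intensity)) ||
      any(items$intensity < 0 | items$intensity > 100)) {
    stop("intensity must be in [0, 100] for every dimension")
  }
  freq <- items$frequency
  is_wb <- items$dimension == "wellbeing"
  if (any(!is.na(freq[is_wb]))) {
    stop("wellbeing is VAS-only: its frequency must be absent (NA)")
  }
  f_other <- freq[!is_wb]
  if (any(is.na(f_other)) || any(f_other != round(f_other)) ||
      any(f_other < 0 | f_other > 6)) {
    stop("frequency must be an integer in 0..6 for every frequency-bearing dimension")
  }
  w <- weights[items$dimension]
  dim_score <- ifelse(is_wb,
                      w * items$intensity / 100,
                      w * (items$intensity / 100) * (freq / 6))
  out <- as.data.frame(as.list(stats::setNames(dim_score, items$dimension)))
  out$gi <- sum(dim_score[items$dimension %in% REQUEST_GI_DIMS])
  out$wso <- sum(dim_score[items$dimension %in% REQUEST_WSO_DIMS])
  out$total <- out$gi + out$wso
  out
}

#' Score the Hospital Anxiety and Depression Scale
#'
#' Sums the 14 four-point (0-3) HADS items into the anxiety and depression
#' subscales (0-21 each) and bands each subscale by the conventional cut
#' points: 0-7 normal, 8-10 suggestive of the respective state, 11+
#' probable mood disorder.
#'
#' @param item_scores integer vector of 14 item scores, each in 0..3, in
#'   instrument order.
#' @param subscale_map character vector of length 14 with entries
#'   `"anxiety"`/`"depression"` (7 of each); the default alternates items,
#'   odd items to anxiety, as in the published instrument layout.
#' @return list with `anxiety`, `depression`, `total`, `anxiety_band`,
#'   `depression_band`.
#' @export
score_hads <- function(item_scores,
                       subscale_map = rep(c("anxiety", "depression"), 7)) {
  if (length(item_scores) != 14) {
    stop("HADS has 14 items; got ", length(item_scores))
  }
  if (any(is.na(item_scores)) || any(item_scores != round(item_scores)) ||
      any(item_scores < 0 | item_scores > 3)) {
    stop("each HADS item must be an integer in 0..3")
  }
  if (length(subscale_map) != 14 ||
      sum(subscale_map == "anxiety") != 7 ||
      sum(subscale_map == "depression") != 7) {
    stop("subscale_map must assign 7 items to each subscale")
  }
  anx <- sum(item_scores[subscale_map == "anxiety"])
  dep <- sum(item_scores[subscale_map == "depression"])
  list(
    anxiety = anx,
    depression = dep,
    total = anx + dep,
    anxiety_band = hads_band(anx),
    depression_band = hads_band(dep)
  )
}

#' Band a HADS subscale score
#'
#' @param score subscale score(s), 0-21.
#' @return character vector: `"normal"` (0-7), `"suggestive"` (8-10) or
#'   `"probable"` (11+).
#' @export
hads_band <- function(score) {
  if (any(is.na(score)) || any(score < 0 | score > 21)) {
    stop("HADS subscale scores lie in [0, 21]")
  }
  ifelse(score >= 11, "probable", ifelse(score >= 8, "suggestive", "normal"))
}

#' Score the GERDyzer quality-of-life instrument
#'
#' Aggregates the ten 0-100 mm VAS dimensions (general well-being,
#' pain/discomfort, physical health, energy, daily activities, leisure,
#' social life, diet, mood, sleep) into a scalar score.  Higher scores mean
#' greater quality-of-life impairment.  The default aggregation is the mean
#' of the dimensions, which keeps the 0-100 interpretation.
#'
#' @param dimension_vas numeric vector of exactly 10 VAS values in [0, 100].
#' @return scalar score in [0, 100].
#' @export
score_gerdyzer <- function(dimension_vas) {
  if (length(dimension_vas) != 10) {
    stop("GERDyzer has 10 dimensions; got ", length(dimension_vas))
  }
  if (any(is.na(dimension_vas)) ||
      any(dimension_vas < 0 | dimension_vas > 100)) {
    stop("each GERDyzer dimension must be in [0, 100]")
  }
  mean(dimension_vas)
}
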