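#' Cap interrupted response times at the Tukey upper fence
#'
#' Total response times far above the bulk of a survey's distribution are
#' read as interruptions (the respondent left and came back), not slow
#' responding, and are replaced by the extreme of the upper whisker of a
#' box plot: `Q3 + 1.5 * IQR`, with quartiles by linear interpolation
#' (type 7). Capping is done per survey (and per device group when devices
#' are analyzed separately), since time distributions differ across both.
#'
#' @param raw_times Positive numeric vector, length >= 4 (quartiles are
#'   unstable below that).
#' @param whisker_mult Multiplier on the IQR (default 1.5).
#' @param quartile_type Quantile algorithm (default 7, linear
#'   interpolation).
#' @return List of class `time_summary`: `capped_times`, `upper_fence`,
#'   `n_capped`, `time_m` (median of capped totals).
#' @export
cap_times <- function(raw_times, whisker_mult = 1.5, quartile_type = 7L) {
  if (length(raw_times) < 4L)
    stop("need at least 4 response times for stable quartiles",
         call. = FALSE)
  if (anyNA(raw_times) || any(raw_times <= 0))
    stop("response times must be positive and complete", call. = FALSE)
  q <- stats::quantile(raw_times, c(0.25, 0.75), type = quartile_type,
                       names = FALSE)
  fence <- q[2L] + whisker_mult * (q[2L] - q[1L])
  capped <- pmin(raw_times, fence)
  structure(
    list(capped_times = capped,
         upper_fence = fence,
         n_capped = sum(raw_times > fence),
         time_m = stats::median(capped)),
    class = "time_summary"
  )
}

#' Per-item response time
#'
#' Total (capped) response time divided by the number of questionnaire
#' items, in seconds per item, so surveys of different lengths are
#' comparable. (Around 2 s/item is the classic fast-responding flag in the
#' screening literature; no cutoff is applied here — the value feeds the
#' detector.)
#'
#' @param capped_time Numeric vector of capped total times (seconds).
#' @param nitems Number of questionnaire items (>= 1).
#' @return Numeric vector, seconds per item.
#' @export
time_per_item <- function(capped_time, nitems) {
  if (nitems < 1L) stop("nitems must be >= 1", call. = FALSE)
  capped_time / nitems
}

#' Survey-level paradata predictors
#'
#' `time_m` is the median of the capped total response times — kept in raw
#' seconds, untransformed, because its purpose is precisely to express
#' differences among surveys — and `nitems` is the questionnaire length.
#' Both are constant within a survey and broadcast to every respondent.
#'
#' @param capped_times Numeric vector of capped total times.
#' @param nitems Questionnaire length.
#' @param n Number of respondents to broadcast to (default
#'   `length(capped_times)`).
#' @return Data frame with columns `time_m` and `nitems`, `n` rows.
#' @export
survey_level <- function(capped_times, nitems, n = length(capped_times)) {
  data.frame(time_m = rep(stats::median(capped_times), n),
             nitems = rep(as.numeric(nitems), n))
}
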