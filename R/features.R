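#' Build the full predictor table for one survey
#'
#' Runs the whole feature stage: extracts the 12-item Likert block,
#' computes the raw block indices, normalizes them for cross-survey
#' comparability, caps the response times at the Tukey upper fence, and
#' attaches the per-item time and the survey-level `time_m` / `nitems`
#' predictors plus the DQS outcome.
#'
#' @param dataset A [survey_dataset()].
#' @return Data frame with columns `respondent_id`, `survey_id`, the 13
#'   predictors of [cier_predictors()], and `outcome`. The capped-time
#'   summary and the chosen Mahalanobis item pair are attached as
#'   attributes `time_summary` and `pair`.
#' @export
compute_features <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  cfg <- dataset$config
  block <- likert_block(dataset)
  raw <- likert_features_raw(block,
                             by_abs_correlation = cfg$pair_by_abs_correlation)
  lik <- normalize_likert(raw, cfg$n_categories, cfg$n_block_items)
  ts <- cap_times(dataset$times_sec)
  para <- survey_level(ts$capped_times, cfg$n_questionnaire_items)
  out <- data.frame(
    respondent_id = dataset$respondent_ids,
    survey_id = cfg$survey_id,
    time = time_per_item(ts$capped_times, cfg$n_questionnaire_items),
    lik,
    para,
    outcome = dataset$outcome,
    check.names = FALSE
  )
  out <- out[, c("respondent_id", "survey_id", cier_predictors(),
                 "outcome")]
  attr(out, "time_summary") <- ts
  attr(out, "pair") <- attr(raw, "pair")
  out
}

#' Build and pool predictor tables for a list of surveys
#'
#' @param datasets List of [survey_dataset()] objects (e.g. the `surveys`
#'   element of [simulate_study()]).
#' @return Pooled data frame, one row per respondent across all surveys.
#' @export
compute_features_all <- function(datasets) {
  do.call(rbind, c(lapply(datasets, compute_features),
                   list(make.row.names = FALSE)))
}
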