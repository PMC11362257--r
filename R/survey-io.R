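#' Describe one survey's layout
#'
#' A survey config records where the screening inputs live inside a wide
#' response table: the position of the block of 12 consecutive Likert items,
#' the number of response categories K, the total questionnaire length, and
#' the directed-question (DQS) items with the category each one instructs.
#' Item positions are 1-based column numbers within the questionnaire item
#' columns (the data columns once respondent id and response time are set
#' aside), matching the convention of reporting item "locations" as column
#' numbers of the data.
#'
#' @param survey_id Character scalar identifying the survey.
#' @param likert_start_col 1-based item-column index of the first of the
#'   `n_block_items` consecutive Likert items used to build predictors.
#' @param n_categories Number of response categories K (>= 2) of that block.
#' @param n_questionnaire_items Total number of item columns ("nitems").
#' @param dqs_cols Integer vector of item-column indices of the DQS items
#'   (two in the original design; at least one required).
#' @param dqs_directed Integer vector, same length as `dqs_cols`: the
#'   category each DQS item instructs the respondent to choose.
#' @param time_col Name (or 1-based raw-CSV index) of the column holding the
#'   total response time in seconds. Default `"time_sec"`.
#' @param device One of `"pc"`, `"smartphone"`, `"unspecified"`. Metadata
#'   only; device-specific models are obtained by running the pipeline on
#'   device-filtered inputs.
#' @param n_block_items Length of the Likert block (default 12).
#' @param block_heterogeneous Logical flag recording that the block mixes
#'   reverse-worded items or items from different constructs (a data-prep
#'   guideline; logged, never enforced).
#' @param pair_by_abs_correlation Use absolute instead of signed Pearson
#'   correlation when picking the item pair for the two-variable
#'   Mahalanobis index.
#' @return An object of class `survey_config`.
#' @export
survey_config <- function(survey_id,
                          likert_start_col,
                          n_categories,
                          n_questionnaire_items,
                          dqs_cols,
                          dqs_directed,
                          time_col = "time_sec",
                          device = c("unspecified", "pc", "smartphone"),
                          n_block_items = 12L,
                          block_heterogeneous = TRUE,
                          pair_by_abs_correlation = FALSE) {
  device <- match.arg(device)
  cfg <- structure(
    list(
      survey_id = as.character(survey_id),
      likert_start_col = as.integer(likert_start_col),
      n_categories = as.integer(n_categories),
      n_questionnaire_items = as.integer(n_questionnaire_items),
      dqs_cols = as.integer(dqs_cols),
      dqs_directed = as.integer(dqs_directed),
      time_col = time_col,
      device = device,
      n_block_items = as.integer(n_block_items),
      block_heterogeneous = isTRUE(block_heterogeneous),
      pair_by_abs_correlation = isTRUE(pair_by_abs_correlation)
    ),
    class = "survey_config"
  )
  validate_survey_config(cfg)
  cfg
}

validate_survey_config <- function(cfg) {
  stopifnot(inherits(cfg, "survey_config"))
  if (cfg$n_categories < 2L)
    stop("n_categories must be >= 2", call. = FALSE)
  if (cfg$n_block_items < 2L)
    stop("n_block_items must be >= 2", call. = FALSE)
  if (cfg$likert_start_col < 1L ||
      cfg$likert_start_col + cfg$n_block_items - 1L > cfg$n_questionnaire_items)
    stop("Likert block [", cfg$likert_start_col, ", ",
         cfg$likert_start_col + cfg$n_block_items - 1L,
         "] does not fit in ", cfg$n_questionnaire_items, " items",
         call. = FALSE)
  if (length(cfg$dqs_cols) < 1L)
    stop("at least one DQS item is required", call. = FALSE)
  if (length(cfg$dqs_cols) != length(cfg$dqs_directed))
    stop("dqs_cols and dqs_directed must have the same length", call. = FALSE)
  if (any(cfg$dqs_cols < 1L | cfg$dqs_cols > cfg$n_questionnaire_items))
    stop("dqs_cols out of range", call. = FALSE)
  if (any(cfg$dqs_directed < 1L | cfg$dqs_directed > cfg$n_categories))
    stop("dqs_directed must lie in 1..K", call. = FALSE)
  invisible(cfg)
}

#' @export
print.survey_config <- function(x, ...) {
  cat("<survey_config> ", x$survey_id, "\n",
      "  items: ", x$n_questionnaire_items,
      ", K = ", x$n_categories,
      ", Likert block @ ", x$likert_start_col,
      " (", x$n_block_items, " items)\n",
      "  DQS @ ", paste(x$dqs_cols, collapse = ", "),
      " directed to ", paste(x$dqs_directed, collapse = ", "),
      "; device: ", x$device, "\n", sep = "")
  invisible(x)
}

#' Assemble a validated survey dataset
#'
#' Bundles one survey's responses, response times, and metadata, and checks
#' the screening preconditions: every entry of the Likert block lies in
#' 1..K, every time is positive, and no required cell is missing.
#'
#' @param config A [survey_config()].
#' @param responses Integer matrix, one row per respondent, one column per
#'   questionnaire item.
#' @param times_sec Positive numeric vector of total response times.
#' @param respondent_ids Optional character vector of ids (default `r1..rn`).
#' @param truth Optional vector of ground-truth behavior labels (used by the
#'   synthetic generator; `NULL` for real data).
#' @return An object of class `survey_dataset` with the DQS outcome already
#'   attached (see [dqs_outcome()]).
#' @export
survey_dataset <- function(config, responses, times_sec,
                           respondent_ids = NULL, truth = NULL) {
  validate_survey_config(config)
  responses <- as.matrix(responses)
  storage.mode(responses) <- "integer"
  n <- nrow(responses)
  if (ncol(responses) != config$n_questionnaire_items)
    stop("responses has ", ncol(responses), " columns; config declares ",
         config$n_questionnaire_items, call. = FALSE)
  if (length(times_sec) != n)
    stop("times_sec length differs from number of respondents", call. = FALSE)
  if (is.null(respondent_ids)) respondent_ids <- paste0("r", seq_len(n))

  block_cols <- config$likert_start_col + seq_len(config$n_block_items) - 1L
  required <- sort(unique(c(block_cols, config$dqs_cols)))
  miss <- which(is.na(responses[, required, drop = FALSE]), arr.ind = TRUE)
  if (nrow(miss) > 0L)
    stop("missing value in required column ", required[miss[1L, 2L]],
         ", row ", miss[1L, 1L], call. = FALSE)
  if (anyNA(times_sec) || any(times_sec <= 0))
    stop("times_sec must be positive and complete (first bad row: ",
         which(is.na(times_sec) | times_sec <= 0)[1L], ")", call. = FALSE)
  block <- responses[, block_cols, drop = FALSE]
  bad <- which(block < 1L | block > config$n_categories, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("Likert response out of range 1..", config$n_categories,
         " at row ", bad[1L, 1L], ", item column ",
         block_cols[bad[1L, 2L]], call. = FALSE)

  ds <- structure(
    list(config = config, responses = responses,
         times_sec = as.numeric(times_sec),
         respondent_ids = as.character(respondent_ids),
         truth = truth, outcome = NULL),
    class = "survey_dataset"
  )
  ds$outcome <- dqs_outcome(ds)
  ds
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("<survey_dataset> ", x$config$survey_id, ": ",
      nrow(x$responses), " respondents x ",
      ncol(x$responses), " items; C/IER (DQS) rate ",
      sprintf("%.3f", mean(x$outcome)), "\n", sep = "")
  invisible(x)
}

#' Extract the Likert block of a survey dataset
#'
#' @param dataset A [survey_dataset()].
#' @return Integer matrix with `n_block_items` columns, entries in 1..K.
#' @export
likert_block <- function(dataset) {
  cfg <- dataset$config
  cols <- cfg$likert_start_col + seq_len(cfg$n_block_items) - 1L
  dataset$responses[, cols, drop = FALSE]
}

#' Directed-question (DQS) outcome
#'
#' A respondent is flagged as a careless / insufficient-effort responder
#' (outcome 1) when they respond incorrectly to at least one DQS item, i.e.
#' choose any category other than the directed one; otherwise 0.
#'
#' @param dataset A [survey_dataset()].
#' @return Integer vector of 0/1, one per respondent.
#' @export
dqs_outcome <- function(dataset) {
  cfg <- dataset$config
  dq <- dataset$responses[, cfg$dqs_cols, drop = FALSE]
  wrong <- sweep(dq, 2L, cfg$dqs_directed, `!=`)
  as.integer(rowSums(wrong) > 0L)
}

#' Read a survey CSV
#'
#' Expects a wide UTF-8 CSV with a header row: an optional `respondent_id`
#' column, the questionnaire item columns, and the response-time column
#' named by `config$time_col` (or given as a raw column index). Item
#' positions in the config refer to the item columns after respondent id
#' and time are set aside. Missing or out-of-range values in the Likert
#' block, the DQS columns, or the time column reject the file with the
#' offending row reported; `drop_incomplete = TRUE` instead removes such
#' rows with a message.
#'
#' @param path CSV path.
#' @param config A [survey_config()].
#' @param drop_incomplete Drop rows with missing required cells instead of
#'   erroring.
#' @return A [survey_dataset()].
#' @export
read_survey <- function(path, config, drop_incomplete = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE)
  tc <- config$time_col
  if (is.numeric(tc)) tc <- names(df)[as.integer(tc)]
  if (!tc %in% names(df))
    stop("time column '", tc, "' not found in ", path, call. = FALSE)
  ids <- if ("respondent_id" %in% names(df)) as.character(df$respondent_id)
         else paste0("r", seq_len(nrow(df)))
  item_df <- df[, setdiff(names(df), c("respondent_id", tc)), drop = FALSE]
  if (ncol(item_df) != config$n_questionnaire_items)
    stop("found ", ncol(item_df), " item columns; config declares ",
         config$n_questionnaire_items, call. = FALSE)
  responses <- as.matrix(item_df)
  times <- as.numeric(df[[tc]])
  if (drop_incomplete) {
    block_cols <- config$likert_start_col + seq_len(config$n_block_items) - 1L
    required <- sort(unique(c(block_cols, config$dqs_cols)))
    ok <- stats::complete.cases(responses[, required, drop = FALSE]) &
      !is.na(times) & times > 0
    if (any(!ok))
      message("read_survey: dropped ", sum(!ok), " incomplete row(s)")
    responses <- responses[ok, , drop = FALSE]
    times <- times[ok]
    ids <- ids[ok]
  }
  survey_dataset(config, responses, times, respondent_ids = ids)
}

#' Write a survey dataset as CSV
#'
#' Inverse of [read_survey()]: writes `respondent_id`, the item columns
#' (`Q1..Qm`), and the time column.
#'
#' @param dataset A [survey_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(dataset, path) {
  m <- ncol(dataset$responses)
  df <- data.frame(respondent_id = dataset$respondent_ids,
                   dataset$responses,
                   check.names = FALSE)
  names(df) <- c("respondent_id", paste0("Q", seq_len(m)))
  tc <- dataset$config$time_col
  if (is.numeric(tc)) tc <- "time_sec"
  df[[tc]] <- dataset$times_sec
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a predictor table as CSV
#'
#' One row per respondent; columns in deterministic order: respondent_id,
#' survey_id, the 13 predictors, outcome.
#'
#' @param features Data frame as produced by [compute_features()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  cols <- c("respondent_id", "survey_id", cier_predictors(), "outcome")
  missing_cols <- setdiff(cols, names(features))
  if (length(missing_cols) > 0L)
    stop("feature table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  utils::write.csv(features[, cols, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a predictor table written by [write_features()]
#'
#' @param path CSV path.
#' @return Data frame with the standard column order.
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(respondent_id = "character",
                                       survey_id = "character"))
  df
}

#' Read / write survey configs as YAML
#'
#' A study config file is a YAML list of survey configs keyed by field name;
#' used by the command-line interface and convenient for scripting.
#'
#' @param path YAML file path.
#' @return A list of [survey_config()] objects.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(x) {
    do.call(survey_config, x)
  })
}

#' @rdname read_study_config
#' @param configs List of [survey_config()] objects.
#' @export
write_study_config <- function(configs, path) {
  yaml::write_yaml(lapply(configs, function(cfg) {
    cfg[c("survey_id", "likert_start_col", "n_categories",
          "n_questionnaire_items", "dqs_cols", "dqs_directed",
          "time_col", "device", "n_block_items",
          "block_heterogeneous", "pair_by_abs_correlation")]
  }), path)
  invisible(path)
}
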