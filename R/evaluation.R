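#' Confusion-matrix metrics for a binary screen
#'
#' Standard definitions: accuracy `(tp+tn)/n`, recall `tp/(tp+fn)`,
#' precision `tp/(tp+fp)`, specificity `tn/(tn+fp)`, balanced accuracy
#' `(recall+specificity)/2` — the latter robust to the class imbalance
#' that makes raw accuracy incomparable across surveys with different
#' careless rates. A ratio with a zero denominator is reported as `NaN`
#' and flagged in the `undefined` column, never silently as 0.
#'
#' @param labels Predicted 0/1 vector.
#' @param truth Observed 0/1 outcome vector.
#' @return One-row data frame: `tp`, `fp`, `tn`, `fn`, `accuracy`,
#'   `recall`, `precision`, `specificity`, `balanced_accuracy`,
#'   `undefined` (comma-separated names of undefined metrics, or "").
#' @export
confusion_metrics <- function(labels, truth) {
  labels <- as.integer(labels)
  truth <- as.integer(truth)
  if (length(labels) != length(truth))
    stop("labels and truth differ in length", call. = FALSE)
  metrics_from_counts(tp = sum(labels == 1L & truth == 1L),
                      fp = sum(labels == 1L & truth == 0L),
                      tn = sum(labels == 0L & truth == 0L),
                      fn = sum(labels == 0L & truth == 1L))
}

metrics_from_counts <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  safe <- function(num, den) if (den > 0) num / den else NaN
  recall <- safe(tp, tp + fn)
  precision <- safe(tp, tp + fp)
  specificity <- safe(tn, tn + fp)
  undef <- c(if (tp + fn == 0) "recall",
             if (tp + fp == 0) "precision",
             if (tn + fp == 0) "specificity")
  data.frame(tp = tp, fp = fp, tn = tn, fn = fn,
             accuracy = safe(tp + tn, n),
             recall = recall,
             precision = precision,
             specificity = specificity,
             balanced_accuracy = (recall + specificity) / 2,
             undefined = paste(undef, collapse = ","))
}

metric_cols <- c("accuracy", "recall", "precision", "specificity",
                 "balanced_accuracy")

#' Balanced multi-survey training set
#'
#' Detection works best when the training outcome is 1 half of the time,
#' so rather than pooling every respondent, each survey contributes `m`
#' randomly sampled careless respondents (outcome 1) and `m` randomly
#' sampled attentive ones, where `m` defaults to the minimum careless
#' count across the supplied surveys. The pooled table has exactly
#' `2 * m * n_surveys` rows and 50% prevalence. A survey with fewer than
#' `m` careless or attentive respondents triggers an error — drop such
#' surveys first (see [drop_low_cier_surveys()]), mirroring the practice
#' of omitting surveys that cannot supply the balancing count.
#'
#' @param features Pooled feature table with `survey_id` and `outcome`
#'   columns (e.g. from [compute_features_all()]).
#' @param m Balancing count per class per survey; default the minimum
#'   per-survey careless count.
#' @param seed Integer seed for the subsampling.
#' @return Data frame of `2 * m * n_surveys` rows, prevalence exactly 0.5;
#'   `m` is attached as attribute `m`.
#' @export
balanced_training_set <- function(features, m = NULL, seed = 1L) {
  stopifnot(all(c("survey_id", "outcome") %in% names(features)))
  ids <- unique(features$survey_id)
  n1 <- vapply(ids, function(s)
    sum(features$outcome == 1L & features$survey_id == s), integer(1L))
  n0 <- vapply(ids, function(s)
    sum(features$outcome == 0L & features$survey_id == s), integer(1L))
  if (is.null(m)) m <- min(n1)
  m <- as.integer(m)
  if (m < 1L)
    stop("balancing count m must be >= 1 (a survey has no C/IERs)",
         call. = FALSE)
  short <- ids[n1 < m | n0 < m]
  if (length(short) > 0L)
    stop("survey(s) ", paste(short, collapse = ", "),
         " have fewer than m = ", m,
         " respondents in a class; drop them before balancing",
         call. = FALSE)
  set.seed(seed)
  rows <- unlist(lapply(ids, function(s) {
    pos <- which(features$survey_id == s & features$outcome == 1L)
    neg <- which(features$survey_id == s & features$outcome == 0L)
    c(sample(pos, m), sample(neg, m))
  }))
  out <- features[rows, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "m") <- m
  out
}

#' Drop surveys that cannot supply a balancing count
#'
#' @param features Pooled feature table with `survey_id` and `outcome`.
#' @param min_count Minimum careless-respondent count a survey must have.
#' @return The table without the short surveys (a warning names them).
#' @export
drop_low_cier_surveys <- function(features, min_count) {
  ids <- unique(features$survey_id)
  n1 <- vapply(ids, function(s)
    sum(features$outcome == 1L & features$survey_id == s), integer(1L))
  short <- ids[n1 < min_count]
  if (length(short) > 0L) {
    warning("dropping survey(s) with fewer than ", min_count,
            " C/IERs: ", paste(short, collapse = ", "))
    features <- features[!features$survey_id %in% short, , drop = FALSE]
  }
  features
}

#' Leave-one-survey-out cross-validation
#'
#' The generalization test the method is built for: each survey in turn is
#' held out entirely; a detector is trained on a balanced training set
#' drawn from all the *other* surveys and applied to *every* respondent of
#' the held-out survey. Per-survey confusion metrics are reported along
#' with two pooled summaries: `mean1`, the plain average of the per-survey
#' metric values (undefined cells excluded, with a disclosure count), and
#' `mean2`, the metrics recomputed on the pooled predictions of all test
#' surveys (its counts are the sums of the per-survey counts).
#'
#' @param features Pooled feature table with `respondent_id`, `survey_id`,
#'   the predictor columns, and `outcome`.
#' @param algorithm `"random_forest"` or `"gradient_boosting"`.
#' @param predictors `"full"`, `"old"`, or explicit column names.
#' @param threshold IRP decision threshold (default 0.5).
#' @param m_mode `"per_fold"` (balancing count recomputed from the
#'   training surveys of each fold — never sees the test survey's counts;
#'   the default) or `"global"` (one count from all surveys).
#' @param hyperparams,tune,seed Passed to [fit_detector()] (the fold index
#'   is added to the seed).
#' @param prevalence Optional numeric vector of artificial careless rates
#'   (e.g. `c(0.105, 0.5)`); for each, positives are downsampled via
#'   [set_prevalence()] and averaged metrics reported.
#' @param n_prev_repeats Resamples per prevalence rate (default 20).
#' @return Object of class `cier_eval_report`: `per_survey` (data frame),
#'   `mean1`, `mean2`, `prevalence_variants`, `predictions` (pooled
#'   respondent-level irp / label / outcome), `m_values`, `threshold`.
#' @export
loso_cv <- function(features,
                    algorithm = c("random_forest", "gradient_boosting"),
                    predictors = "full",
                    threshold = 0.5,
                    m_mode = c("per_fold", "global"),
                    hyperparams = list(),
                    tune = TRUE,
                    seed = 1L,
                    prevalence = NULL,
                    n_prev_repeats = 20L) {
  algorithm <- match.arg(algorithm)
  m_mode <- match.arg(m_mode)
  ids <- unique(features$survey_id)
  if (length(ids) < 2L)
    stop("leave-one-survey-out needs at least two surveys", call. = FALSE)
  global_m <- min(vapply(ids, function(s)
    sum(features$outcome == 1L & features$survey_id == s), integer(1L)))
  per_survey <- vector("list", length(ids))
  preds <- vector("list", length(ids))
  m_values <- integer(length(ids))
  for (k in seq_along(ids)) {
    s <- ids[k]
    train_feat <- features[features$survey_id != s, , drop = FALSE]
    test_feat <- features[features$survey_id == s, , drop = FALSE]
    m <- if (m_mode == "global") global_m else NULL
    balanced <- balanced_training_set(train_feat, m = m, seed = seed + k)
    m_values[k] <- attr(balanced, "m")
    det <- fit_detector(balanced, algorithm = algorithm,
                        predictors = predictors,
                        hyperparams = hyperparams, tune = tune,
                        seed = seed + k)
    irp <- predict_irp(det, test_feat)
    labels <- classify_irp(irp, threshold)
    cm <- confusion_metrics(labels, test_feat$outcome)
    per_survey[[k]] <- cbind(survey_id = s, cm)
    preds[[k]] <- data.frame(respondent_id = test_feat$respondent_id,
                             survey_id = s, irp = irp, label = labels,
                             outcome = test_feat$outcome)
  }
  per_survey <- do.call(rbind, c(per_survey, list(make.row.names = FALSE)))
  predictions <- do.call(rbind, c(preds, list(make.row.names = FALSE)))
  report <- structure(
    list(per_survey = per_survey,
         mean1 = mean1_of(per_survey),
         mean2 = confusion_metrics(predictions$label,
                                   predictions$outcome),
         prevalence_variants = NULL,
         predictions = predictions,
         m_values = stats::setNames(m_values, ids),
         threshold = threshold,
         algorithm = algorithm),
    class = "cier_eval_report"
  )
  if (!is.null(prevalence)) {
    report$prevalence_variants <- lapply(
      stats::setNames(prevalence, paste0(100 * prevalence, "%")),
      function(rate) {
        per <- do.call(rbind, lapply(ids, function(s) {
          sub <- predictions[predictions$survey_id == s, ]
          set_prevalence(sub$label, sub$outcome, rate,
                         seed = seed, n_repeats = n_prev_repeats)
        }))
        list(mean1 = mean1_of(per),
             mean2 = set_prevalence(predictions$label,
                                    predictions$outcome, rate,
                                    seed = seed,
                                    n_repeats = n_prev_repeats))
      })
  }
  report
}

# Average the per-survey metric values, excluding undefined (NaN) cells;
# the number of exclusions per metric is attached as attribute
# "n_excluded".
mean1_of <- function(per_survey) {
  out <- as.data.frame(lapply(per_survey[metric_cols], function(v)
    mean(v[is.finite(v)])))
  attr(out, "n_excluded") <- vapply(per_survey[metric_cols], function(v)
    sum(!is.finite(v)), integer(1L))
  out
}

#' @export
print.cier_eval_report <- function(x, digits = 3L, ...) {
  cat("<cier_eval_report> ", x$algorithm, ", threshold ", x$threshold,
      ", ", nrow(x$per_survey), " surveys\n", sep = "")
  tab <- x$per_survey
  tab[metric_cols] <- lapply(tab[metric_cols], round, digits)
  print(tab[, c("survey_id", metric_cols)], row.names = FALSE)
  cat("Mean 1:", paste(metric_cols,
                       round(unlist(x$mean1[metric_cols]), digits),
                       sep = " = ", collapse = ", "), "\n")
  cat("Mean 2:", paste(metric_cols,
                       round(unlist(x$mean2[metric_cols]), digits),
                       sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Artificially set the careless prevalence of a test set
#'
#' To compare detection metrics across settings with different careless
#' rates, positives (outcome 1) are randomly downsampled — attentive
#' respondents are left untouched — until the careless rate equals
#' `target_rate`; metrics are computed on the reduced set and averaged
#' over `n_repeats` resamples. The retained positive count solves
#' `n_pos / (n_pos + n_neg) = target_rate`.
#'
#' @param labels Predicted 0/1 vector.
#' @param truth Observed 0/1 outcome vector.
#' @param target_rate Desired careless rate in (0, 1).
#' @param seed Integer seed.
#' @param n_repeats Number of resamples to average (default 20).
#' @return One-row data frame of averaged counts and metrics, with the
#'   retained positive count as column `n_pos_kept`.
#' @export
set_prevalence <- function(labels, truth, target_rate, seed = 1L,
                           n_repeats = 20L) {
  labels <- as.integer(labels)
  truth <- as.integer(truth)
  pos <- which(truth == 1L)
  neg <- which(truth == 0L)
  n_keep <- round(target_rate / (1 - target_rate) * length(neg))
  if (n_keep > length(pos))
    stop("target rate ", target_rate, " unachievable: at most ",
         round(length(pos) / (length(pos) + length(neg)), 4),
         " with the available positives", call. = FALSE)
  if (n_keep < 1L)
    stop("target rate ", target_rate, " retains no positives",
         call. = FALSE)
  set.seed(seed)
  reps <- lapply(seq_len(n_repeats), function(r) {
    keep <- c(sample(pos, n_keep), neg)
    confusion_metrics(labels[keep], truth[keep])
  })
  reps <- do.call(rbind, reps)
  out <- as.data.frame(lapply(
    reps[c("tp", "fp", "tn", "fn", metric_cols)], function(v)
      mean(v[is.finite(v)])))
  out$n_pos_kept <- n_keep
  out
}
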