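#' Tune the random-forest split-candidate count by out-of-bag error
#'
#' For each candidate `mtry` (the number of predictors sampled at each
#' partition) a forest is grown and its out-of-bag misclassification error
#' — the error on the observations not drawn in each bootstrap sample —
#' is recorded; the candidate with the smallest OOB error wins, ties going
#' to the smaller (simpler) `mtry`.
#'
#' @param features Data frame of predictor columns.
#' @param outcome Binary 0/1 vector.
#' @param grid Candidate `mtry` values (default all of `1:ncol(features)`).
#' @param ntree Trees per forest (default 500).
#' @param seed Integer seed.
#' @return List: `mtry` (chosen value), `oob_error` (named vector over the
#'   grid).
#' @export
tune_random_forest <- function(features, outcome,
                               grid = seq_len(ncol(features)),
                               ntree = 500L, seed = 1L) {
  check_training_data(features, outcome)
  grid <- sort(unique(as.integer(grid)))
  if (any(grid < 1L | grid > ncol(features)))
    stop("mtry grid must lie in 1..", ncol(features), call. = FALSE)
  y <- factor(outcome, levels = c(0L, 1L))
  oob <- vapply(grid, function(m) {
    set.seed(seed + m)  # one stream per candidate; reproducible
    fit <- randomForest::randomForest(x = features, y = y,
                                      ntree = ntree, mtry = m)
    fit$err.rate[ntree, "OOB"]
  }, numeric(1L))
  names(oob) <- grid
  list(mtry = grid[which.min(oob)], oob_error = oob)
}

#' Tune the gradient-boosting tree depth by tenfold cross-validation
#'
#' The depth of the largest tree is chosen by stratified ten-part
#' cross-validation on the training data, minimizing the CV log-loss;
#' ties go to the shallower depth. The number of boosting rounds is set
#' by early stopping on the CV folds (patience `patience`, cap
#' `max_rounds`); the learning rate is fixed.
#'
#' @param features Data frame of predictor columns.
#' @param outcome Binary 0/1 vector.
#' @param depth_grid Candidate maximum depths.
#' @param nfold Number of CV folds (default 10).
#' @param eta Learning rate (default 0.1).
#' @param max_rounds Cap on boosting rounds (default 500).
#' @param patience Early-stopping patience in rounds (default 20).
#' @param seed Integer seed.
#' @return List: `max_depth`, `nrounds` (best round at that depth),
#'   `cv_logloss` (named vector over the grid).
#' @export
tune_gradient_boosting <- function(features, outcome,
                                   depth_grid = c(2L, 3L, 4L, 6L),
                                   nfold = 10L, eta = 0.1,
                                   max_rounds = 500L, patience = 20L,
                                   seed = 1L) {
  check_training_data(features, outcome)
  depth_grid <- sort(unique(as.integer(depth_grid)))
  d <- xgboost::xgb.DMatrix(as.matrix(features), label = outcome,
                            nthread = 1)
  loss <- numeric(length(depth_grid))
  best_round <- integer(length(depth_grid))
  for (i in seq_along(depth_grid)) {
    set.seed(seed + depth_grid[i])
    cv <- xgboost::xgb.cv(
      params = list(objective = "binary:logistic",
                    max_depth = depth_grid[i], eta = eta, nthread = 1),
      data = d, nrounds = max_rounds, nfold = nfold,
      metrics = "logloss", early_stopping_rounds = patience,
      stratified = TRUE, verbose = 0
    )
    log <- as.data.frame(cv$evaluation_log)
    best <- which.min(log$test_logloss_mean)
    loss[i] <- log$test_logloss_mean[best]
    best_round[i] <- best
  }
  names(loss) <- depth_grid
  pick <- which.min(loss)
  list(max_depth = depth_grid[pick], nrounds = best_round[pick],
       cv_logloss = loss)
}

check_training_data <- function(features, outcome) {
  if (length(outcome) != nrow(features))
    stop("outcome length differs from feature rows", call. = FALSE)
  if (length(unique(outcome)) < 2L)
    stop("training data contains a single class", call. = FALSE)
  bad <- names(features)[vapply(features, function(v)
    any(!is.finite(v)), logical(1L))]
  if (length(bad) > 0L)
    stop("non-finite feature values in column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Fit a careless-responder detector
#'
#' Trains a tree ensemble mapping the 13 screening predictors to the
#' probability that a respondent is a careless / insufficient-effort
#' responder (the inattentive response probability, IRP). Hyperparameters
#' not supplied are tuned first: the random forest's `mtry` by OOB error
#' ([tune_random_forest()]), the boosting depth by tenfold CV
#' ([tune_gradient_boosting()]).
#'
#' @param train Data frame containing the predictor columns and an
#'   `outcome` column (as built by [balanced_training_set()]).
#' @param algorithm `"random_forest"` or `"gradient_boosting"`.
#' @param predictors `"full"` (all 13) or `"old"` (time, ls, maha,
#'   maha_p), or an explicit character vector of column names.
#' @param hyperparams Optional named list; recognized entries
#'   `mtry`, `ntree` (forest) and `max_depth`, `eta`, `nrounds`
#'   (boosting). Missing entries are tuned / defaulted.
#' @param tune Tune missing hyperparameters (default TRUE). With
#'   `tune = FALSE` the forest uses `floor(sqrt(p))` and boosting depth 3.
#' @param seed Integer seed; refitting with the same data and seed gives
#'   identical predictions.
#' @return Object of class `cier_detector`.
#' @export
fit_detector <- function(train,
                         algorithm = c("random_forest",
                                       "gradient_boosting"),
                         predictors = "full",
                         hyperparams = list(),
                         tune = TRUE,
                         seed = 1L) {
  algorithm <- match.arg(algorithm)
  feature_names <- if (length(predictors) == 1L &&
                       predictors %in% c("full", "old"))
    cier_predictors(predictors) else as.character(predictors)
  missing_cols <- setdiff(c(feature_names, "outcome"), names(train))
  if (length(missing_cols) > 0L)
    stop("training table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  x <- train[, feature_names, drop = FALSE]
  y <- as.integer(train$outcome)
  check_training_data(x, y)

  if (algorithm == "random_forest") {
    ntree <- hyperparams$ntree %||% 500L
    mtry <- hyperparams$mtry
    tuning <- NULL
    if (is.null(mtry)) {
      if (tune) {
        tuning <- tune_random_forest(x, y, ntree = ntree, seed = seed)
        mtry <- tuning$mtry
      } else mtry <- max(1L, floor(sqrt(ncol(x))))
    }
    set.seed(seed)
    model <- randomForest::randomForest(
      x = x, y = factor(y, levels = c(0L, 1L)), ntree = ntree, mtry = mtry
    )
    hp <- list(ntree = ntree, mtry = mtry)
  } else {
    eta <- hyperparams$eta %||% 0.1
    max_depth <- hyperparams$max_depth
    nrounds <- hyperparams$nrounds
    tuning <- NULL
    if (is.null(max_depth) || is.null(nrounds)) {
      if (tune && is.null(max_depth)) {
        tuning <- tune_gradient_boosting(x, y, eta = eta, seed = seed)
        max_depth <- tuning$max_depth
        nrounds <- nrounds %||% tuning$nrounds
      } else {
        max_depth <- max_depth %||% 3L
        nrounds <- nrounds %||% 100L
      }
    }
    set.seed(seed)
    model <- xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = max_depth, eta = eta, nthread = 1),
      data = xgboost::xgb.DMatrix(as.matrix(x), label = y, nthread = 1),
      nrounds = nrounds, verbose = 0
    )
    hp <- list(max_depth = max_depth, eta = eta, nrounds = nrounds)
  }
  structure(
    list(algorithm = algorithm,
         model = model,
         hyperparams = hp,
         tuning = tuning,
         feature_names = feature_names,
         training_meta = list(seed = seed, n_train = nrow(x),
                              class_balance = mean(y))),
    class = "cier_detector"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cier_detector <- function(x, ...) {
  hp <- paste(names(x$hyperparams), unlist(x$hyperparams),
              sep = " = ", collapse = ", ")
  cat("<cier_detector> ", x$algorithm, " (", hp, ")\n",
      "  ", length(x$feature_names), " predictors; trained on n = ",
      x$training_meta$n_train, " (class balance ",
      sprintf("%.2f", x$training_meta$class_balance), ")\n", sep = "")
  invisible(x)
}

#' Inattentive response probability (IRP)
#'
#' The detector's class-1 probability per respondent: for the random
#' forest the fraction of trees voting "careless", for boosting the
#' logistic-transformed score.
#'
#' @param detector A [fit_detector()] result.
#' @param features Data frame containing the detector's predictor columns.
#' @return Numeric vector in `[0, 1]`.
#' @export
predict_irp <- function(detector, features) {
  stopifnot(inherits(detector, "cier_detector"))
  missing_cols <- setdiff(detector$feature_names, names(features))
  if (length(missing_cols) > 0L)
    stop("feature table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  x <- features[, detector$feature_names, drop = FALSE]
  if (detector$algorithm == "random_forest") {
    as.numeric(stats::predict(detector$model, x, type = "prob")[, "1"])
  } else {
    as.numeric(stats::predict(
      detector$model,
      xgboost::xgb.DMatrix(as.matrix(x), nthread = 1)))
  }
}

#' Threshold an IRP vector into careless / attentive labels
#'
#' A respondent is flagged when their inattentive response probability
#' reaches the threshold (inclusive at the boundary). Raising the
#' threshold flags only respondents with a stronger careless tendency and
#' never adds positives.
#'
#' @param irp Numeric vector in `[0, 1]`.
#' @param threshold Decision threshold in (0, 1); default 0.5.
#' @return Integer 0/1 vector.
#' @export
classify_irp <- function(irp, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly in (0, 1)", call. = FALSE)
  as.integer(irp >= threshold)
}

#' Permutation importance (mean decrease in accuracy)
#'
#' For each predictor, its column is shuffled among respondents
#' `n_repeats` times and the loss in classification accuracy (at the
#' given threshold) relative to the unshuffled data is averaged: the
#' larger the decrease, the more the detector relies on that predictor.
#' A predictor the model never uses scores about zero.
#'
#' @param detector A [fit_detector()] result.
#' @param features Data frame with the predictor columns.
#' @param outcome Binary 0/1 truth vector.
#' @param n_repeats Shuffles per predictor (default 10).
#' @param threshold Classification threshold (default 0.5).
#' @param seed Integer seed.
#' @return Data frame: `predictor`, `mean_decrease_accuracy`, `sd`.
#' @export
permutation_importance <- function(detector, features, outcome,
                                   n_repeats = 10L, threshold = 0.5,
                                   seed = 1L) {
  stopifnot(inherits(detector, "cier_detector"))
  outcome <- as.integer(outcome)
  base_acc <- mean(classify_irp(predict_irp(detector, features),
                                threshold) == outcome)
  set.seed(seed)
  res <- lapply(detector$feature_names, function(f) {
    drops <- vapply(seq_len(n_repeats), function(r) {
      shuffled <- features
      shuffled[[f]] <- sample(shuffled[[f]])
      acc <- mean(classify_irp(predict_irp(detector, shuffled),
                               threshold) == outcome)
      base_acc - acc
    }, numeric(1L))
    c(mean = mean(drops), sd = stats::sd(drops))
  })
  data.frame(predictor = detector$feature_names,
             mean_decrease_accuracy = vapply(res, `[[`, numeric(1L),
                                             "mean"),
             sd = vapply(res, `[[`, numeric(1L), "sd"))
}
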