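#' Specification for a synthetic multi-survey study
#'
#' The generator emulates the data regime the screening method is designed
#' for: several web surveys with different category counts, questionnaire
#' lengths and pacing; attentive respondents driven by correlated latent
#' traits with a middle-category tendency; and a mixture of careless
#' behaviors (uniform random responding, straightlining, adjacent-category
#' drift, fast random responding) whose directed-question (DQS) answers
#' follow the same behavior, so DQS failure is coupled to true
#' carelessness. Per-survey arguments are recycled to `n_surveys`.
#'
#' Defaults: six surveys of 400 respondents; K spans 5..10; questionnaire
#' lengths 60..150 items; careless rates from 0.25 to 0.5 (the band seen
#' in practice for unscreened web panels); attentive pace about 6 s/item.
#'
#' @param n_surveys Number of surveys.
#' @param n_respondents Respondents per survey.
#' @param n_categories Response categories K per survey.
#' @param nitems Questionnaire length per survey.
#' @param likert_start_col Item-column of the first block item per survey.
#' @param base_time_s Median attentive total response time (seconds) per
#'   survey; default 6 s/item times `nitems`.
#' @param careless_rate Proportion of careless respondents per survey.
#' @param careless_mix Named weights over the four careless behaviors;
#'   normalized to sum to 1.
#' @param latent_loading Factor loading of block items on the respondent's
#'   trait, in (0, 1).
#' @param n_reverse_items Number of reverse-keyed items inside the block.
#' @param middle_bias Extra width (on the latent normal scale) given to the
#'   middle response category, emulating the middle-category tendency.
#' @param dqs_miss_attentive Probability an attentive respondent fails one
#'   DQS item.
#' @param time_lognorm_sigma Log-scale SD of total response times.
#' @param careless_speed_factor Multiplier (< 1) on the response time of
#'   fast random responders.
#' @param seed Integer seed; the study is a pure function of the spec.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_surveys = 6L,
                            n_respondents = 400L,
                            n_categories = c(5L, 6L, 7L, 8L, 9L, 10L),
                            nitems = c(60L, 90L, 120L, 75L, 150L, 100L),
                            likert_start_col = c(10L, 20L, 35L, 15L, 50L, 25L),
                            base_time_s = NULL,
                            careless_rate = seq(0.25, 0.5,
                                                length.out = n_surveys),
                            careless_mix = c(uniform_random = 0.40,
                                             straightline = 0.30,
                                             adjacent_walk = 0.15,
                                             fast_random = 0.15),
                            latent_loading = 0.75,
                            n_reverse_items = 4L,
                            middle_bias = 0.3,
                            dqs_miss_attentive = 0.01,
                            time_lognorm_sigma = 0.4,
                            careless_speed_factor = 0.35,
                            seed = 20260919L) {
  n_surveys <- as.integer(n_surveys)
  rec <- function(x) rep_len(x, n_surveys)
  nitems <- rec(as.integer(nitems))
  if (is.null(base_time_s)) base_time_s <- 6 * nitems
  behaviors <- c("uniform_random", "straightline",
                 "adjacent_walk", "fast_random")
  if (!setequal(names(careless_mix), behaviors))
    stop("careless_mix must be named over: ",
         paste(behaviors, collapse = ", "), call. = FALSE)
  careless_mix <- careless_mix[behaviors] / sum(careless_mix)
  spec <- structure(
    list(n_surveys = n_surveys,
         n_respondents = rec(as.integer(n_respondents)),
         n_categories = rec(as.integer(n_categories)),
         nitems = nitems,
         likert_start_col = rec(as.integer(likert_start_col)),
         base_time_s = rec(base_time_s),
         careless_rate = rec(careless_rate),
         careless_mix = careless_mix,
         latent_loading = latent_loading,
         n_reverse_items = as.integer(n_reverse_items),
         middle_bias = middle_bias,
         dqs_miss_attentive = dqs_miss_attentive,
         time_lognorm_sigma = time_lognorm_sigma,
         careless_speed_factor = careless_speed_factor,
         seed = as.integer(seed)),
    class = "simulation_spec"
  )
  with(spec, {
    stopifnot(all(careless_rate >= 0 & careless_rate <= 1),
              latent_loading > 0, latent_loading < 1,
              n_reverse_items >= 0, n_reverse_items <= 12,
              middle_bias >= 0,
              dqs_miss_attentive >= 0, dqs_miss_attentive <= 1,
              careless_speed_factor > 0, careless_speed_factor < 1,
              all(likert_start_col + 11L <= nitems))
  })
  spec
}

# Category cut points on the latent N(0,1) scale: equal-probability
# thresholds, with the middle category (the middle two for even K)
# widened by `middle_bias`.
category_cutpoints <- function(K, middle_bias = 0) {
  cuts <- stats::qnorm(seq_len(K - 1L) / K)
  if (middle_bias > 0 && K >= 3L) {
    if (K %% 2L == 1L) {
      m <- (K + 1L) %/% 2L
      cuts[m - 1L] <- cuts[m - 1L] - middle_bias / 2
      cuts[m] <- cuts[m] + middle_bias / 2
    } else {
      lo <- K %/% 2L - 1L
      hi <- K %/% 2L + 1L
      if (lo >= 1L) cuts[lo] <- cuts[lo] - middle_bias / 2
      if (hi <= K - 1L) cuts[hi] <- cuts[hi] + middle_bias / 2
    }
    cuts <- sort(cuts)
  }
  cuts
}

discretize_latent <- function(latent, cuts) {
  findInterval(latent, cuts) + 1L
}

#' Simulate attentive respondents
#'
#' Each respondent carries one latent trait per ~12-item construct,
#' theta ~ N(0,1); item responses discretize
#' `loading * d_k * theta + noise` (unit total variance, `d_k = -1` for
#' reverse-keyed items) through equal-probability normal thresholds
#' widened at the middle by `middle_bias`. DQS items are answered as
#' directed with probability `1 - dqs_miss_attentive` each; total response
#' time is log-normal around `base_time_s`.
#'
#' @param n Number of respondents.
#' @param K Response categories.
#' @param nitems Questionnaire length.
#' @param dqs_cols,dqs_directed DQS positions and directed categories.
#' @param spec A [simulation_spec()] (supplies loadings, biases, times).
#' @param base_time_s Median total time for this survey.
#' @return List: `responses` (n x nitems), `times` (length n).
#' @export
simulate_attentive <- function(n, K, nitems, dqs_cols, dqs_directed,
                               spec, base_time_s) {
  lam <- spec$latent_loading
  cuts <- category_cutpoints(K, spec$middle_bias)
  n_constructs <- max(1L, ceiling(nitems / 12L))
  construct_of <- rep(seq_len(n_constructs), each = 12L)[seq_len(nitems)]
  theta <- matrix(stats::rnorm(n * n_constructs), n, n_constructs)
  # reverse-keyed items: the first n_reverse_items of each construct's
  # second half, mirroring blocks built from mixed-keyed scales
  direction <- rep(1, nitems)
  if (spec$n_reverse_items > 0L) {
    for (cstr in seq_len(n_constructs)) {
      idx <- which(construct_of == cstr)
      nrev <- min(spec$n_reverse_items, length(idx) %/% 2L)
      if (nrev > 0L)
        direction[idx[seq.int(length(idx) - nrev + 1L, length(idx))]] <- -1
    }
  }
  eps <- matrix(stats::rnorm(n * nitems, sd = sqrt(1 - lam^2)), n, nitems)
  latent <- lam * theta[, construct_of, drop = FALSE] *
    rep(direction, each = n) + eps
  responses <- matrix(discretize_latent(latent, cuts), n, nitems)
  # DQS: mostly compliant; a miss lands on a random wrong category
  for (j in seq_along(dqs_cols)) {
    ans <- rep(dqs_directed[j], n)
    miss <- stats::runif(n) < spec$dqs_miss_attentive
    if (any(miss)) {
      wrong <- setdiff(seq_len(K), dqs_directed[j])
      ans[miss] <- sample(wrong, sum(miss), replace = TRUE)
    }
    responses[, dqs_cols[j]] <- ans
  }
  times <- stats::rlnorm(n, meanlog = log(base_time_s),
                         sdlog = spec$time_lognorm_sigma)
  list(responses = responses, times = times)
}

#' Simulate careless respondents
#'
#' Behavior is drawn from `spec$careless_mix` per respondent and applied
#' to the *entire* questionnaire, DQS items included, so directed
#' questions fail at the behavior's natural rate: uniform random
#' responding (iid uniform over 1..K), straightlining (one random category
#' repeated everywhere), adjacent-category drift (a reflected +/-1 random
#' walk over categories), and fast random responding (uniform responses
#' with the response time multiplied by `careless_speed_factor`).
#'
#' @inheritParams simulate_attentive
#' @return List: `responses`, `times`, `behavior` (character labels).
#' @export
simulate_careless <- function(n, K, nitems, dqs_cols, dqs_directed,
                              spec, base_time_s) {
  behaviors <- names(spec$careless_mix)
  behavior <- sample(behaviors, n, replace = TRUE,
                     prob = spec$careless_mix)
  responses <- matrix(0L, n, nitems)
  for (i in seq_len(n)) {
    responses[i, ] <- switch(
      behavior[i],
      uniform_random = ,
      fast_random = sample.int(K, nitems, replace = TRUE),
      straightline = rep(sample.int(K, 1L), nitems),
      adjacent_walk = {
        steps <- sample(c(-1L, 1L), nitems - 1L, replace = TRUE)
        pos <- cumsum(c(sample.int(K, 1L), steps))
        # reflect off 1 and K
        period <- 2L * (K - 1L)
        r <- (pos - 1L) %% period
        as.integer(ifelse(r < K, r + 1L, period - r + 1L))
      }
    )
  }
  times <- stats::rlnorm(n, meanlog = log(base_time_s),
                         sdlog = spec$time_lognorm_sigma)
  fast <- behavior == "fast_random"
  times[fast] <- times[fast] * spec$careless_speed_factor
  list(responses = responses, times = times, behavior = behavior)
}

#' Simulate a full multi-survey study
#'
#' Draws each survey with its own K, length, pacing and careless rate;
#' careless status is Bernoulli per respondent. The recorded `outcome` is
#' *recomputed from the DQS responses* via [dqs_outcome()], never copied
#' from the ground-truth labels, so label noise (careless respondents who
#' happen to comply, attentive slips) flows through exactly as it would in
#' the field. Ground truth is carried alongside in `truth`.
#'
#' @param spec A [simulation_spec()].
#' @return Object of class `simulated_study`: list with `surveys` (list of
#'   [survey_dataset()] with `truth` labels) and `spec`.
#' @export
simulate_study <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  survey_seeds <- sample.int(.Machine$integer.max, spec$n_surveys)
  surveys <- vector("list", spec$n_surveys)
  for (s in seq_len(spec$n_surveys)) {
    set.seed(survey_seeds[s])
    K <- spec$n_categories[s]
    nitems <- spec$nitems[s]
    start <- spec$likert_start_col[s]
    # DQS outside the block, directed to two distinct non-middle
    # categories (middle-category tendency would make the middle too easy)
    dqs_cols <- c(max(1L, start - 2L), min(nitems, start + 14L))
    dqs_directed <- c(2L, K - 1L)
    cfg <- survey_config(
      survey_id = sprintf("S%02d", s),
      likert_start_col = start,
      n_categories = K,
      n_questionnaire_items = nitems,
      dqs_cols = dqs_cols,
      dqs_directed = dqs_directed
    )
    n <- spec$n_respondents[s]
    careless <- stats::runif(n) < spec$careless_rate[s]
    n_c <- sum(careless)
    att <- simulate_attentive(n - n_c, K, nitems, dqs_cols, dqs_directed,
                              spec, spec$base_time_s[s])
    responses <- matrix(0L, n, nitems)
    times <- numeric(n)
    truth <- character(n)
    responses[!careless, ] <- att$responses
    times[!careless] <- att$times
    truth[!careless] <- "attentive"
    if (n_c > 0L) {
      car <- simulate_careless(n_c, K, nitems, dqs_cols, dqs_directed,
                               spec, spec$base_time_s[s])
      responses[careless, ] <- car$responses
      times[careless] <- car$times
      truth[careless] <- car$behavior
    }
    surveys[[s]] <- survey_dataset(cfg, responses, times,
                                   respondent_ids =
                                     sprintf("S%02d_r%04d", s, seq_len(n)),
                                   truth = truth)
  }
  structure(list(surveys = surveys, spec = spec),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("<simulated_study> ", length(x$surveys), " surveys, seed ",
      x$spec$seed, "\n", sep = "")
  for (s in x$surveys) print(s)
  invisible(x)
}

#' Write a simulated study to disk
#'
#' One CSV per survey ([write_survey()]), a study-level YAML config
#' ([write_study_config()]), and a truth CSV with the ground-truth
#' behavior labels.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  configs <- lapply(study$surveys, `[[`, "config")
  write_study_config(configs, file.path(dir, "study.yaml"))
  truth <- list()
  for (s in study$surveys) {
    write_survey(s, file.path(dir, paste0(s$config$survey_id, ".csv")))
    truth[[s$config$survey_id]] <- data.frame(
      respondent_id = s$respondent_ids,
      survey_id = s$config$survey_id,
      truth = s$truth,
      outcome = s$outcome
    )
  }
  utils::write.csv(do.call(rbind, c(truth, list(make.row.names = FALSE))),
                   file.path(dir, "truth.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}
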