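# Naive reference implementations of the sequence indices, written as
# plain loops so they can arbitrate the vectorized versions.

ls_brute <- function(seq) {
  best <- 1L
  run <- 1L
  for (t in seq_along(seq)[-1L]) {
    run <- if (seq[t] == seq[t - 1L]) run + 1L else 1L
    best <- max(best, run)
  }
  best
}

ac_brute <- function(seq) {
  total <- 0L
  for (t in seq_len(length(seq) - 1L))
    if (abs(seq[t + 1L] - seq[t]) == 1L) total <- total + 1L
  total
}

mac_brute <- function(seq) {
  best <- 0L
  run <- 0L
  for (t in seq_len(length(seq) - 1L)) {
    run <- if (abs(seq[t + 1L] - seq[t]) == 1L) run + 1L else 0L
    best <- max(best, run)
  }
  best
}

cr_brute <- function(seq) {
  k <- 0L
  seen <- integer(0L)
  for (v in seq) if (!v %in% seen) {
    seen <- c(seen, v)
    k <- k + 1L
  }
  c(r2c = as.integer(k <= 2L), r3c = as.integer(k <= 3L))
}

# A small deterministic survey: n respondents, m items, K categories,
# with the Likert block at `start`; responses cycle through categories
# unless overridden.
toy_config <- function(K = 5L, m = 20L, start = 3L,
                       dqs_cols = c(1L, 16L), dqs_directed = c(2L, 4L)) {
  survey_config("toy", likert_start_col = start, n_categories = K,
                n_questionnaire_items = m, dqs_cols = dqs_cols,
                dqs_directed = dqs_directed)
}

toy_dataset <- function(n = 8L, cfg = toy_config(), seed = 1L,
                        times = NULL) {
  set.seed(seed)
  K <- cfg$n_categories
  m <- cfg$n_questionnaire_items
  responses <- matrix(sample.int(K, n * m, replace = TRUE), n, m)
  # make every respondent DQS-compliant unless a test overrides
  for (j in seq_along(cfg$dqs_cols))
    responses[, cfg$dqs_cols[j]] <- cfg$dqs_directed[j]
  if (is.null(times)) times <- stats::rlnorm(n, log(300), 0.3)
  survey_dataset(cfg, responses, times)
}

# Per-survey careless counts of a published 16-survey screening study
# (smartphone and PC respondent pools); used to exercise the balancing
# arithmetic at realistic sizes.
smart_counts <- data.frame(
  n = c(961, 806, 782, 786, 817, 903, 778, 811, 609, 496, 580, 806,
        566, 703, 1411, 721),
  cier = c(439, 187, 303, 243, 326, 403, 240, 346, 233, 187, 270, 274,
           293, 348, 401, 289)
)
pc_counts <- data.frame(
  n = c(639, 794, 818, 814, 483, 541, 822, 789, 591, 504, 620, 794,
        434, 297, 89, 279),
  cier = c(366, 210, 331, 219, 243, 280, 269, 292, 206, 196, 258, 297,
           206, 162, 37, 121)
)

# Minimal feature-shaped table with given class counts per survey; the
# balancing constructor only needs survey_id and outcome.
counts_to_features <- function(counts) {
  do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    n1 <- counts$cier[i]
    n0 <- counts$n[i] - n1
    data.frame(survey_id = sprintf("S%02d", i),
               respondent_id = sprintf("S%02d_r%05d", i,
                                       seq_len(n0 + n1)),
               outcome = rep(c(1L, 0L), c(n1, n0)))
  }))
}

# Small pooled feature table from a simulated study, reused by the
# detector and evaluation tests to avoid regenerating per test.
small_study_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- simulation_spec(n_surveys = 4L, n_respondents = 150L,
                              seed = 424242L)
      cache <<- compute_features_all(simulate_study(spec)$surveys)
    }
    cache
  }
})
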