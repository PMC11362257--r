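test_that("simulation_spec validates and recycles per-survey fields", {
  spec <- simulation_spec(n_surveys = 3L, n_respondents = 100L,
                          n_categories = 5L)
  expect_length(spec$n_categories, 3L)
  expect_equal(sum(spec$careless_mix), 1)
  expect_error(simulation_spec(careless_mix = c(uniform_random = 1)),
               "careless_mix")
  expect_error(simulation_spec(careless_speed_factor = 1.5))
})

test_that("attentive responses are uniform when the trait is off", {
  spec <- simulation_spec(seed = 1L, middle_bias = 0,
                          latent_loading = 1e-9, n_reverse_items = 0L)
  set.seed(100)
  att <- simulate_attentive(5000L, K = 5L, nitems = 12L,
                            dqs_cols = integer(0), dqs_directed = integer(0),
                            spec = spec, base_time_s = 300)
  counts <- table(factor(att$responses[, 1L], levels = 1:5))
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("the latent trait induces inter-item correlation, negative for
reverse items", {
  spec <- simulation_spec(seed = 1L, latent_loading = 0.8,
                          n_reverse_items = 0L, middle_bias = 0)
  set.seed(101)
  att <- simulate_attentive(3000L, K = 5L, nitems = 12L,
                            dqs_cols = integer(0), dqs_directed = integer(0),
                            spec = spec, base_time_s = 300)
  cm <- cor(att$responses)
  expect_gt(mean(cm[upper.tri(cm)]), 0.3)

  spec_rev <- simulation_spec(seed = 1L, latent_loading = 0.8,
                              n_reverse_items = 4L, middle_bias = 0)
  set.seed(102)
  att_rev <- simulate_attentive(3000L, K = 5L, nitems = 12L,
                                dqs_cols = integer(0),
                                dqs_directed = integer(0),
                                spec = spec_rev, base_time_s = 300)
  cm <- cor(att_rev$responses)
  expect_lt(max(cm[1:8, 9:12]), 0)   # reverse vs straight items
  expect_gt(min(cm[9:12, 9:12][upper.tri(diag(4))]), 0)
})

test_that("middle_bias piles extra mass on the middle category", {
  spec0 <- simulation_spec(seed = 1L, middle_bias = 0,
                           latent_loading = 1e-9, n_reverse_items = 0L)
  spec1 <- simulation_spec(seed = 1L, middle_bias = 0.6,
                           latent_loading = 1e-9, n_reverse_items = 0L)
  set.seed(103)
  a0 <- simulate_attentive(4000L, 5L, 12L, integer(0), integer(0),
                           spec0, 300)
  set.seed(103)
  a1 <- simulate_attentive(4000L, 5L, 12L, integer(0), integer(0),
                           spec1, 300)
  expect_gt(mean(a1$responses == 3L), mean(a0$responses == 3L) + 0.05)
})

test_that("careless behaviors produce their signature patterns", {
  spec <- simulation_spec(seed = 1L)
  set.seed(104)
  n <- 600L
  car <- simulate_careless(n, K = 5L, nitems = 40L,
                           dqs_cols = c(3L, 30L), dqs_directed = c(2L, 4L),
                           spec = spec, base_time_s = 240)
  block <- car$responses[, 10:21]
  ls <- apply(block, 1L, long_string)
  ac <- apply(block, 1L, function(s) adjacent_runs(s)[["ac"]])

  straight <- car$behavior == "straightline"
  expect_true(all(ls[straight] == 12L))
  walk <- car$behavior == "adjacent_walk"
  expect_true(all(ac[walk] == 11L))  # a no-stay walk is always adjacent
  expect_true(all(car$responses %in% 1:5))

  # uniform responders fail at least one of two DQS with prob 1 - 1/K^2
  unif <- car$behavior %in% c("uniform_random", "fast_random")
  fails <- car$responses[unif, 3L] != 2L | car$responses[unif, 30L] != 4L
  expect_equal(mean(fails), 1 - 1 / 25, tolerance = 0.05)
})

test_that("simulate_study is a pure function of spec and seed", {
  spec <- simulation_spec(n_surveys = 2L, n_respondents = 80L, seed = 7L)
  s1 <- simulate_study(spec)
  s2 <- simulate_study(spec)
  expect_identical(s1$surveys[[1L]]$responses, s2$surveys[[1L]]$responses)
  expect_identical(s1$surveys[[2L]]$times_sec, s2$surveys[[2L]]$times_sec)
  s3 <- simulate_study(simulation_spec(n_surveys = 2L,
                                       n_respondents = 80L, seed = 8L))
  expect_false(identical(s1$surveys[[1L]]$responses,
                         s3$surveys[[1L]]$responses))
})

test_that("study-level structure follows the simulation settings", {
  spec <- simulation_spec(seed = 99L)
  study <- simulate_study(spec)
  expect_length(study$surveys, 6L)
  Ks <- vapply(study$surveys, function(s) s$config$n_categories,
               integer(1L))
  expect_identical(Ks, spec$n_categories)

  # empirical careless rate within 3 binomial s.e. of the target
  for (i in seq_along(study$surveys)) {
    s <- study$surveys[[i]]
    rate <- mean(s$truth != "attentive")
    target <- spec$careless_rate[i]
    se <- sqrt(target * (1 - target) / length(s$truth))
    expect_lt(abs(rate - target), 3 * se + 1e-9)
  }

  # outcome is recomputed from DQS, not copied from truth:
  # attentive respondents fail at most at the slip rate
  att_fail <- unlist(lapply(study$surveys, function(s)
    s$outcome[s$truth == "attentive"]))
  expect_lte(mean(att_fail), 1 - (1 - spec$dqs_miss_attentive)^2 + 0.01)
})

test_that("careless respondents are faster and more repetitive on average", {
  study <- simulate_study(simulation_spec(n_surveys = 3L,
                                          n_respondents = 300L,
                                          seed = 55L))
  feats <- compute_features_all(study$surveys)
  truth <- unlist(lapply(study$surveys, `[[`, "truth"))
  careless <- truth != "attentive"
  expect_lt(mean(feats$time[careless]), mean(feats$time[!careless]))
  expect_gt(mean(feats$ls[careless]), mean(feats$ls[!careless]))
})

test_that("write_study emits per-survey CSVs, config and truth table", {
  dir <- withr::local_tempdir()
  study <- simulate_study(simulation_spec(n_surveys = 2L,
                                          n_respondents = 40L,
                                          seed = 3L))
  write_study(study, dir)
  expect_true(file.exists(file.path(dir, "study.yaml")))
  expect_true(file.exists(file.path(dir, "S01.csv")))
  truth <- utils::read.csv(file.path(dir, "truth.csv"))
  expect_identical(nrow(truth), 80L)
  # round-trip through the config reproduces the outcome
  cfgs <- read_study_config(file.path(dir, "study.yaml"))
  back <- read_survey(file.path(dir, "S01.csv"), cfgs[[1L]])
  expect_identical(back$outcome, study$surveys[[1L]]$outcome)
})
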