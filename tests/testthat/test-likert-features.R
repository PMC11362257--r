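test_that("long_string finds the longest constant run", {
  expect_identical(long_string(rep(5L, 12L)), 12L)
  expect_identical(long_string(rep(c(1L, 2L), 6L)), 1L)
  seq <- c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 1L, 1L, 1L, 1L, 2L)
  expect_identical(long_string(seq), ls_brute(seq))
  expect_identical(long_string(seq), 4L)
})

test_that("category_restriction flags 2- and 3-category users", {
  expect_identical(category_restriction(rep(c(2L, 5L), 6L)),
                   c(r2c = 1L, r3c = 1L))
  expect_identical(category_restriction(c(1L, 3L, 4L, 1L, 3L, 4L)),
                   c(r2c = 0L, r3c = 1L))
  expect_identical(category_restriction(c(1L, 2L, 3L, 4L, 1L, 2L)),
                   c(r2c = 0L, r3c = 0L))
})

test_that("adjacent_runs reproduces the worked example and edge cases", {
  expect_identical(adjacent_runs(c(1L, 2L, 3L, 4L, 2L, 1L)),
                   c(ac = 4L, mac = 3L))
  expect_identical(adjacent_runs(rep(3L, 12L)), c(ac = 0L, mac = 0L))
  # monotone sweep up then down: every transition adjacent
  expect_identical(adjacent_runs(c(1L, 2L, 3L, 4L, 5L, 4L, 3L, 2L)),
                   c(ac = 7L, mac = 7L))
})

test_that("sequence indices match brute force on all 5^6 sequences", {
  grid <- as.matrix(expand.grid(rep(list(1:5), 6L)))
  storage.mode(grid) <- "integer"
  for (i in seq_len(nrow(grid))) {
    s <- grid[i, ]
    expect_identical(long_string(s), ls_brute(s))
    ar <- adjacent_runs(s)
    expect_identical(ar[["ac"]], ac_brute(s))
    expect_identical(ar[["mac"]], mac_brute(s))
    expect_identical(category_restriction(s), cr_brute(s))
  }
})

test_that("index invariants hold on random blocks", {
  set.seed(11)
  for (rep in 1:200) {
    K <- sample(2:10, 1L)
    s <- sample.int(K, 12L, replace = TRUE)
    ls <- long_string(s)
    ar <- adjacent_runs(s)
    cr <- category_restriction(s)
    expect_true(ls >= 1L && ls <= 12L)
    expect_true(ar[["mac"]] >= 0L && ar[["mac"]] <= ar[["ac"]])
    expect_true(ar[["ac"]] <= 11L)
    expect_true(cr[["r2c"]] <= cr[["r3c"]])
    if (ls == 12L) {
      expect_identical(unname(ar), c(0L, 0L))
      expect_identical(cr[["r2c"]], 1L)
    }
  }
})

test_that("reference moments exclude straightliners, with fallback", {
  set.seed(2)
  block <- matrix(sample.int(5L, 40L * 12L, replace = TRUE), 40L)
  # no constant rows almost surely -> exclusion vacuous
  ref <- reference_moments(block)
  expect_false(ref$excluded_all_flag)
  expect_equal(ref$mean_vec, colMeans(block))
  expect_equal(ref$cov, cov(block))

  # half the rows straightline: moments come from the other half only
  block2 <- block
  block2[1:20, ] <- 3L
  ref2 <- reference_moments(block2)
  expect_identical(ref2$n_used, 20L)
  expect_equal(ref2$mean_vec, colMeans(block2[21:40, ]))
  expect_equal(ref2$cov, cov(block2[21:40, ]))

  # nearly everything excluded -> fallback to all rows, flagged
  block3 <- block
  block3[1:38, ] <- 4L
  expect_warning(ref3 <- reference_moments(block3), "all")
  expect_true(ref3$excluded_all_flag)
  expect_identical(ref3$n_used, 40L)
})

test_that("mahalanobis index: zero at the center, closed form at df = 2", {
  set.seed(3)
  block <- matrix(sample.int(7L, 60L * 12L, replace = TRUE), 60L)
  ref <- reference_moments(block)
  at_center <- mahalanobis_index(ref$mean_vec, ref)
  expect_equal(at_center$maha, 0)
  expect_equal(at_center$maha_p, 1)

  # two-variable toy with identity covariance: x - mean = (1,1)
  # gives maha = 2 and chi-square(2) survival exp(-1)
  ref2 <- structure(list(mean_vec = c(0, 0), cov = diag(2),
                         n_used = 100L, keep = rep(TRUE, 100L),
                         excluded_all_flag = FALSE),
                    class = "reference_moments")
  res <- mahalanobis_index(c(1, 1), ref2)
  expect_equal(res$maha, 2)
  expect_equal(res$maha_p, exp(-1), tolerance = 1e-12)
})

test_that("maha_p decreases strictly as maha grows", {
  ref2 <- structure(list(mean_vec = c(0, 0), cov = diag(2)),
                    class = "reference_moments")
  d <- seq(0.5, 6, by = 0.5)
  p <- mahalanobis_index(cbind(d, 0), ref2)$maha_p
  expect_true(all(diff(p) < 0))
})

test_that("singular covariance is rescued by the escalating ridge", {
  # two identical non-constant rows duplicated: rank-deficient covariance
  base <- matrix(rep(c(1L, 3L, 2L, 5L, 4L, 2L, 1L, 3L, 5L, 2L, 4L, 1L),
                     times = 6L), nrow = 6L, byrow = TRUE)
  base[, 1L] <- 1:6  # one informative column, the rest collinear
  # 6 rows < the full-rank minimum, so the fallback warning fires too
  ref <- suppressWarnings(reference_moments(base))
  expect_message(res <- mahalanobis_index(base, ref), "ridge")
  expect_true(all(is.finite(res$maha)))
  expect_true(all(res$maha >= 0))
})

test_that("top_correlated_pair finds duplicates, planted pairs and ties", {
  set.seed(4)
  block <- matrix(rnorm(200L * 12L), 200L)
  block[, 7L] <- block[, 3L]  # r = 1
  expect_identical(top_correlated_pair(block), c(3L, 7L))

  # planted r ~ 0.9 pair among independent noise, vs exhaustive scan
  block2 <- matrix(rnorm(300L * 12L), 300L)
  block2[, 9L] <- 0.9 * block2[, 2L] + sqrt(1 - 0.81) * rnorm(300L)
  pair <- top_correlated_pair(block2)
  cm <- cor(block2)
  best <- c(NA, NA); best_r <- -Inf
  for (i in 1:11) for (j in (i + 1):12)
    if (cm[i, j] > best_r) { best_r <- cm[i, j]; best <- c(i, j) }
  expect_identical(pair, as.integer(best))
  expect_identical(pair, c(2L, 9L))

  # exact tie: col2 = col1 and col6 = col5 -> lexicographically first
  block3 <- matrix(rnorm(100L * 6L), 100L)
  block3[, 2L] <- block3[, 1L]
  block3[, 6L] <- block3[, 5L]
  expect_identical(top_correlated_pair(block3), c(1L, 2L))

  expect_error(top_correlated_pair(matrix(2L, 10L, 12L)), "non-constant")
})

test_that("signed vs absolute correlation pick can differ", {
  set.seed(5)
  x <- rnorm(500L)
  block <- cbind(x, -x + 0.1 * rnorm(500L),
                 matrix(rnorm(500L * 10L), 500L))
  signed <- top_correlated_pair(block)
  absolute <- top_correlated_pair(block, by_abs = TRUE)
  expect_identical(absolute, c(1L, 2L))  # strongest |r| is the negative pair
  expect_false(identical(signed, absolute))
})

test_that("absdevi is the L1 distance from the reference mean", {
  set.seed(6)
  block <- matrix(sample.int(5L, 30L * 12L, replace = TRUE), 30L)
  ref <- reference_moments(block)
  expect_equal(absdevi(ref$mean_vec, ref), 0)
  expect_equal(absdevi(ref$mean_vec + 1, ref), 12)
  x <- block[4L, ]
  expect_equal(absdevi(x, ref), sum(abs(x - ref$mean_vec)))
})

test_that("normalize_likert applies the printed transformation rules", {
  raw <- data.frame(ls = 12L, r2c = 1L, r3c = 1L, ac = 4L, mac = 2L,
                    maha = 28.8, maha_p = 0.2, maha2 = 1.5,
                    maha2_p = 0.47, absdevi = 18)
  out <- normalize_likert(raw, n_categories = 6L)
  expect_equal(out$ls, 1.0)
  expect_equal(out$ac, 2.0)        # K * AC / 12 = 6*4/12
  expect_equal(out$mac, 1.0)
  expect_equal(out$maha, 0.2)      # 28.8 / 144
  expect_equal(out$absdevi, 0.25)  # 18 / (12*6)
  # untouched fields pass through
  expect_equal(out[c("r2c", "r3c", "maha_p", "maha2", "maha2_p")],
               raw[c("r2c", "r3c", "maha_p", "maha2", "maha2_p")])
})

test_that("features are stable under joint row permutation", {
  set.seed(7)
  block <- matrix(sample.int(6L, 50L * 12L, replace = TRUE), 50L)
  f1 <- likert_features_raw(block)
  perm <- sample(50L)
  f2 <- likert_features_raw(block[perm, ])
  expect_equal(f2[order(perm), ], f1, ignore_attr = TRUE)
})
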