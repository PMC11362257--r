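#' The thirteen screening predictors, in canonical order
#'
#' The detector consumes exactly these columns, in this order: per-item
#' response time (`time`), long-string (`ls`), the category-restriction
#' flags (`r2c`, `r3c`), adjacent-category run statistics (`ac`, `mac`),
#' the 12-item Mahalanobis index and its chi-square p-value (`maha`,
#' `maha_p`), the two-item variant (`maha2`, `maha2_p`), the sum of
#' absolute deviations (`absdevi`), and the survey-level median time and
#' questionnaire length (`time_m`, `nitems`). The stored values are the
#' cross-survey normalized versions.
#'
#' @param set `"full"` for all 13; `"old"` for the four predictors used in
#'   earlier response-quality work (time, ls, maha, maha_p).
#' @return Character vector of predictor names.
#' @export
cier_predictors <- function(set = c("full", "old")) {
  set <- match.arg(set)
  full <- c("time", "ls", "r2c", "r3c", "ac", "mac",
            "maha", "maha_p", "maha2", "maha2_p", "absdevi",
            "time_m", "nitems")
  if (set == "old") full[c(1L, 2L, 7L, 8L)] else full
}

#' Long-string index
#'
#' Length of the longest run of consecutive responses in the same category.
#' A straightliner who repeats one category across the whole block scores
#' the block length; a respondent who never repeats scores 1.
#'
#' @param seq Integer vector of Likert responses.
#' @return Integer in `[1, length(seq)]`.
#' @export
long_string <- function(seq) {
  if (length(seq) < 1L) stop("empty response sequence", call. = FALSE)
  max(rle(as.vector(seq))$lengths)
}

#' Category-restriction flags
#'
#' `r2c` indicates that at most two distinct categories were used across
#' the block, `r3c` at most three. `r2c = 1` implies `r3c = 1`.
#'
#' @param seq Integer vector of Likert responses.
#' @return Named integer vector `c(r2c = , r3c = )`.
#' @export
category_restriction <- function(seq) {
  k_used <- length(unique(as.vector(seq)))
  c(r2c = as.integer(k_used <= 2L), r3c = as.integer(k_used <= 3L))
}

#' Adjacent-category run statistics
#'
#' A transition is *adjacent* when consecutive responses differ by exactly
#' one category. `ac` counts adjacent transitions over the whole sequence;
#' `mac` is the longest unbroken chain of adjacent transitions (0 when
#' there is none). For the sequence 1,2,3,4,2,1 the transitions 1-2, 2-3,
#' 3-4, 2-1 are adjacent, so `ac = 4`, and the longest chain is 1-2, 2-3,
#' 3-4, so `mac = 3`.
#'
#' @param seq Integer vector of Likert responses (length >= 2).
#' @return Named integer vector `c(ac = , mac = )`, with
#'   `0 <= mac <= ac <= length(seq) - 1`.
#' @export
adjacent_runs <- function(seq) {
  seq <- as.vector(seq)
  if (length(seq) < 2L) stop("need at least two responses", call. = FALSE)
  adj <- abs(diff(seq)) == 1L
  r <- rle(adj)
  mac <- if (any(adj)) max(r$lengths[r$values]) else 0L
  c(ac = as.integer(sum(adj)), mac = as.integer(mac))
}

#' Reference moments for the Mahalanobis indices
#'
#' Mean vector and covariance matrix of the Likert block, estimated after
#' excluding respondents whose long-string equals the block length (pure
#' straightliners), so that careless rows do not contaminate the reference
#' distribution. If fewer than `min_rows` respondents survive the
#' exclusion the moments fall back to all rows and `excluded_all_flag`
#' is set (with a warning): `ncol + 2` is the smallest count for which the
#' covariance can be non-degenerate.
#'
#' @param block Integer matrix (respondents x block items).
#' @param min_rows Minimum retained rows before falling back (default
#'   `ncol(block) + 2`).
#' @return List of class `reference_moments`: `mean_vec`, `cov`, `n_used`,
#'   `keep` (logical row filter), `excluded_all_flag`.
#' @export
reference_moments <- function(block, min_rows = ncol(block) + 2L) {
  block <- as.matrix(block)
  n <- nrow(block)
  if (n < 2L) stop("need at least two respondents", call. = FALSE)
  ls_all <- apply(block, 1L, long_string)
  keep <- ls_all < ncol(block)
  fallback <- sum(keep) < min_rows
  if (fallback) {
    warning("only ", sum(keep), " rows left after excluding constant rows; ",
            "using all ", n, " rows for the reference moments")
    keep <- rep(TRUE, n)
  }
  sub <- block[keep, , drop = FALSE]
  structure(
    list(mean_vec = colMeans(sub),
         cov = stats::cov(sub),
         n_used = nrow(sub),
         keep = keep,
         excluded_all_flag = fallback),
    class = "reference_moments"
  )
}

# Inverse of a covariance matrix with an escalating ridge: eps *
# mean(diag(cov)) * I with eps 1e-6, x10 up to 1e-3, before erroring.
# Few categories or small reference samples readily produce singular
# covariances; the screening indices still need an inverse.
solve_cov <- function(cov, context = "covariance") {
  scale <- mean(diag(cov))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  for (eps in c(0, 10^(-6:-3))) {
    reg <- cov + diag(eps * scale, nrow(cov))
    inv <- tryCatch(solve(reg), error = function(e) NULL)
    if (!is.null(inv)) {
      if (eps > 0)
        message("ridge ", format(eps), " applied to ", context)
      return(inv)
    }
  }
  stop("irreparably singular ", context, call. = FALSE)
}

#' Squared Mahalanobis distance and chi-square p-value
#'
#' Computes the quadratic form
#' \eqn{(x - \bar x)' \Sigma^{-1} (x - \bar x)} of each respondent's block
#' responses against the filtered reference moments, i.e. the *squared*
#' Mahalanobis distance (no square root is taken, so the chi-square
#' reference is coherent), together with the upper-tail probability of a
#' chi-square with degrees of freedom equal to the number of items: the
#' p-value of the test that the respondent does not deviate from the mean
#' vector.
#'
#' @param x Numeric matrix (rows = respondents) or a single vector.
#' @param ref A [reference_moments()] object.
#' @return Data frame with columns `maha` (>= 0) and `maha_p` in (0, 1].
#' @export
mahalanobis_index <- function(x, ref) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  df <- length(ref$mean_vec)
  if (ncol(x) != df)
    stop("x has ", ncol(x), " columns; reference has ", df, call. = FALSE)
  inv <- solve_cov(ref$cov)
  d2 <- stats::mahalanobis(x, center = ref$mean_vec, cov = inv,
                           inverted = TRUE)
  d2 <- pmax(d2, 0)
  data.frame(maha = d2, maha_p = stats::pchisq(d2, df = df,
                                               lower.tail = FALSE))
}

#' Most highly correlated item pair
#'
#' Finds the pair of block items with the highest Pearson correlation,
#' computed on the same straightliner-filtered rows used for the reference
#' moments. By default the *signed* correlation is maximized; with
#' `by_abs = TRUE` the absolute value is (consequential when the block
#' contains reverse-worded items). Ties resolve to the lexicographically
#' smallest pair.
#'
#' @param block Integer matrix (respondents x block items).
#' @param keep Logical row filter (typically `ref$keep`); default all rows.
#' @param by_abs Maximize `|r|` instead of `r`.
#' @return Integer vector `c(i, j)` with `i < j`.
#' @export
top_correlated_pair <- function(block, keep = NULL, by_abs = FALSE) {
  block <- as.matrix(block)
  if (!is.null(keep)) block <- block[keep, , drop = FALSE]
  vars <- apply(block, 2L, stats::var)
  usable <- which(is.finite(vars) & vars > 0)
  if (length(usable) < 2L)
    stop("need at least two non-constant items to pick a pair",
         call. = FALSE)
  cm <- suppressWarnings(stats::cor(block))
  if (by_abs) cm <- abs(cm)
  best <- c(NA_integer_, NA_integer_)
  best_r <- -Inf
  p <- ncol(block)
  for (i in seq_len(p - 1L)) {
    for (j in seq.int(i + 1L, p)) {
      r <- cm[i, j]
      if (is.finite(r) && r > best_r) {
        best_r <- r
        best <- c(i, j)
      }
    }
  }
  if (!is.finite(best_r))
    stop("no correlated pair could be computed", call. = FALSE)
  as.integer(best)
}

#' Sum of absolute deviations from the reference mean vector
#'
#' A covariance-free companion to the Mahalanobis index: the L1 distance
#' of each respondent's block responses from the reference mean vector.
#'
#' @param x Numeric matrix (rows = respondents) or a single vector.
#' @param ref A [reference_moments()] object.
#' @return Non-negative numeric vector.
#' @export
absdevi <- function(x, ref) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  rowSums(abs(sweep(x, 2L, ref$mean_vec)))
}

#' Raw Likert-block predictors for every respondent
#'
#' Applies [long_string()], [category_restriction()], [adjacent_runs()],
#' the Mahalanobis indices ([mahalanobis_index()] on all items and on the
#' [top_correlated_pair()]) and [absdevi()] row-wise.
#'
#' @param block Integer matrix (respondents x block items), entries 1..K.
#' @param by_abs_correlation Passed to [top_correlated_pair()].
#' @return Data frame of raw (untransformed) per-respondent features:
#'   `ls`, `r2c`, `r3c`, `ac`, `mac`, `maha`, `maha_p`, `maha2`,
#'   `maha2_p`, `absdevi`; the chosen pair and the reference moments are
#'   attached as attributes `pair` and `ref`.
#' @export
likert_features_raw <- function(block, by_abs_correlation = FALSE) {
  block <- as.matrix(block)
  ls <- apply(block, 1L, long_string)
  cr <- t(apply(block, 1L, category_restriction))
  ar <- t(apply(block, 1L, adjacent_runs))
  ref <- reference_moments(block)
  m12 <- mahalanobis_index(block, ref)
  pair <- top_correlated_pair(block, keep = ref$keep,
                              by_abs = by_abs_correlation)
  sub <- block[ref$keep, pair, drop = FALSE]
  ref2 <- structure(
    list(mean_vec = colMeans(sub), cov = stats::cov(sub),
         n_used = nrow(sub), keep = ref$keep,
         excluded_all_flag = ref$excluded_all_flag),
    class = "reference_moments"
  )
  m2 <- mahalanobis_index(block[, pair, drop = FALSE], ref2)
  out <- data.frame(
    ls = as.integer(ls),
    r2c = cr[, "r2c"], r3c = cr[, "r3c"],
    ac = ar[, "ac"], mac = ar[, "mac"],
    maha = m12$maha, maha_p = m12$maha_p,
    maha2 = m2$maha, maha2_p = m2$maha_p,
    absdevi = absdevi(block, ref)
  )
  attr(out, "pair") <- pair
  attr(out, "ref") <- ref
  out
}

#' Normalize Likert-block predictors for cross-survey comparability
#'
#' The raw indices depend on the number of block items and, for some, on
#' the number of response categories K; the normalizations remove those
#' dependencies so surveys with different layouts can be pooled:
#' `ls / n_items`, `K * ac / n_items`, `K * mac / n_items`,
#' `maha / n_items^2`, `absdevi / (n_items * K)`. The binary flags, the
#' p-values, and the fixed-dimension two-item index pass through
#' unchanged.
#'
#' @param raw Data frame from [likert_features_raw()].
#' @param n_categories K.
#' @param n_block_items Block length (default 12).
#' @return Data frame with the normalized `ls`, `r2c`, `r3c`, `ac`, `mac`,
#'   `maha`, `maha_p`, `maha2`, `maha2_p`, `absdevi` columns.
#' @export
normalize_likert <- function(raw, n_categories, n_block_items = 12L) {
  if (n_categories < 2L) stop("n_categories must be >= 2", call. = FALSE)
  K <- n_categories
  m <- n_block_items
  data.frame(
    ls = raw$ls / m,
    r2c = raw$r2c, r3c = raw$r3c,
    ac = K * raw$ac / m,
    mac = K * raw$mac / m,
    maha = raw$maha / m^2,
    maha_p = raw$maha_p,
    maha2 = raw$maha2, maha2_p = raw$maha2_p,
    absdevi = raw$absdevi / (m * K)
  )
}
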