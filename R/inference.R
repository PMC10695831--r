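# Significance machinery: exact / sampled mean-difference permutation
# test and the two-tailed paired t-test.

# unrank the `rank`-th (1-based, lexicographic) k-combination of 1..n
unrank_combination <- function(rank, n, k) {
  out <- integer(k)
  r <- rank - 1
  x <- 1L
  for (i in seq_len(k)) {
    repeat {
      c_rest <- choose(n - x, k - i)
      if (r < c_rest) break
      r <- r - c_rest
      x <- x + 1L
    }
    out[i] <- x
    x <- x + 1L
  }
  out
}

# lexicographic rank (1-based) of a sorted k-combination of 1..n
rank_combination <- function(comb, n) {
  k <- length(comb)
  r <- 0
  prev <- 0L
  for (i in seq_len(k)) {
    if (comb[i] > prev + 1L)
      r <- r + sum(choose(n - seq(prev + 1L, comb[i] - 1L), k - i))
    prev <- comb[i]
  }
  r + 1
}

#' Mean-difference permutation test
#'
#' Tests the difference between two sets of replicate measurements with
#' the statistic mean(a) - mean(b), assuming exchangeability only under
#' the null. All distinct reassignments of the pooled values into groups
#' of the original sizes are enumerated exactly when their number is at
#' most `max_exhaustive`; otherwise `n_samples` distinct assignments are
#' drawn without replacement (the observed labelling always included).
#' The p-value is the proportion of evaluated assignments whose statistic
#' is at least as extreme as the observed one, counting the observed
#' labelling itself — the inclusive convention, which makes the smallest
#' attainable two-sided p for two fully separated groups of four exactly
#' 2/70 (0.029).
#'
#' @param a,b numeric vectors of replicate measurements (each >= 2).
#' @param alternative "two.sided" (|mean(a)-mean(b)| at least as large),
#'   "greater" (mean(a)-mean(b) at least as large) or "less".
#' @param max_exhaustive enumerate exactly when choose(na+nb, na) is at
#'   most this, default 1e6.
#' @param n_samples number of assignments drawn when sampling, default 1e5.
#' @param seed RNG seed for the sampled branch.
#' @return An object of class `permutation_test`: `p_value`,
#'   `statistic` (observed mean difference), `n_assignments`,
#'   `exhaustive`, `alternative`, `seed`.
#' @export
#' @examples
#' permutation_test(c(1, 2, 3, 4), c(10, 11, 12, 13))$p_value  # 2/70
permutation_test <- function(a, b,
                             alternative = c("two.sided", "greater", "less"),
                             max_exhaustive = 1e6, n_samples = 1e5,
                             seed = NULL) {
  alternative <- match.arg(alternative)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 replicates")
  if (!all(is.finite(c(a, b)))) stop("measurements must be finite")
  pooled <- c(a, b)
  na <- length(a); nb <- length(b); n <- na + nb
  total <- choose(n, na)
  S <- sum(pooled)
  obs <- mean(a) - mean(b)

  exhaustive <- total <= max_exhaustive || n_samples >= total
  if (exhaustive) {
    idx <- utils::combn(n, na)
    s1 <- colSums(matrix(pooled[idx], nrow = na))
    evaluated <- total
  } else {
    if (!is.null(seed)) set.seed(seed)
    ranks <- sample(total, n_samples)
    obs_rank <- rank_combination(seq_len(na), n)
    if (!obs_rank %in% ranks) ranks <- c(obs_rank, ranks)
    s1 <- vapply(ranks, function(r)
      sum(pooled[unrank_combination(r, n, na)]), numeric(1))
    evaluated <- length(ranks)
  }
  stat <- s1 / na - (S - s1) / nb
  eps <- 1e-9 * max(1, abs(obs))
  count <- switch(alternative,
    two.sided = sum(abs(stat) >= abs(obs) - eps),
    greater = sum(stat >= obs - eps),
    less = sum(stat <= obs + eps))
  structure(list(p_value = count / evaluated, statistic = obs,
                 n_assignments = evaluated, exhaustive = exhaustive,
                 alternative = alternative, seed = seed),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("permutation test (%s, %s over %d assignments)\n",
              x$alternative,
              if (x$exhaustive) "exhaustive" else "sampled",
              x$n_assignments))
  cat(sprintf("  mean difference = %.4g, P = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}

#' Two-tailed paired t-test
#'
#' Classical paired t statistic on the within-pair differences with a
#' two-tailed p-value from the t distribution on n - 1 degrees of
#' freedom; used for the urea-stability comparisons.
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return list with `p_value`, `t`, `df`, `mean_difference`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0)
    stop("degenerate input: within-pair differences have zero variance")
  ht <- stats::t.test(x, y, paired = TRUE, alternative = "two.sided")
  list(p_value = ht$p.value, t = unname(ht$statistic),
       df = unname(ht$parameter), mean_difference = unname(ht$estimate))
}
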