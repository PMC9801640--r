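# Independent brute-force oracles and small fixture builders. These
# deliberately re-derive results from first principles (exhaustive scans,
# enumeration) so they share no code with the implementation they check.

# exhaustive O(n^2) k-nearest-neighbour oracle; ties by ascending row index
oracle_knn <- function(X, i, k, labels = NULL, restrict = NULL,
                       exclude_self = TRUE) {
  n <- nrow(X)
  cand <- setdiff(seq_len(n), if (exclude_self) i else integer(0))
  if (!is.null(restrict)) cand <- cand[labels[cand] == restrict]
  d <- vapply(cand, function(j) sqrt(sum((X[j, ] - X[i, ])^2)), numeric(1))
  cand[order(d, cand)][seq_len(k)]
}

# exhaustive Tomek-link oracle: mutual single nearest neighbours of
# opposite class; returns the majority-class member of each link
oracle_tomek_deletions <- function(X, labels, majority) {
  n <- nrow(X)
  nn <- vapply(seq_len(n), function(i) oracle_knn(X, i, 1L), integer(1))
  del <- integer(0)
  for (i in seq_len(n)) {
    j <- nn[i]
    if (nn[j] == i && labels[i] != labels[j] && i < j)
      del <- c(del, if (labels[i] == majority) i else j)
  }
  sort(unique(del))
}

# full 2^n sign-flip enumeration of the signed-rank null; returns the
# two-sided p-value of T = min(R+, R-) for the given (possibly tied) ranks
oracle_signrank_p <- function(ranks, T_stat) {
  n <- length(ranks)
  total <- sum(ranks)
  rplus <- vapply(0:(2^n - 1), function(mask) {
    sum(ranks[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0])
  }, numeric(1))
  tmin <- pmin(rplus, total - rplus)
  mean(tmin <= T_stat + 1e-9)
}

# direct Friedman chi-square from first principles (rank, average, plug in)
oracle_friedman_chi2 <- function(tbl) {
  rk <- t(apply(tbl, 1, function(v) rank(-v, ties.method = "average")))
  R <- colMeans(rk)
  N <- nrow(tbl); k <- ncol(tbl)
  12 * N / (k * (k + 1)) * (sum(R^2) - k * (k + 1)^2 / 4)
}

# two well-separated Gaussian blobs; majority "A" at the origin
separated_blobs <- function(n_a = 20, n_b = 10, gap = 50, p = 2, seed = 42) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_a * p), n_a, p),
             matrix(rnorm(n_b * p) + gap, n_b, p))
  labeled_dataset(X, c(rep("A", n_a), rep("B", n_b)))
}

random_dataset <- function(n, p, seed, imbalance = 0.5) {
  set.seed(seed)
  n_b <- max(2L, round(n * imbalance / (1 + imbalance)))
  labeled_dataset(matrix(rnorm(n * p), n, p),
                  c(rep("A", n - n_b), rep("B", n_b)))
}

expect_same_rows <- function(a, b) {
  key <- function(X) sort(apply(round(X, 10), 1, paste, collapse = "|"))
  expect_identical(key(a), key(b))
}
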