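## Standard two-sided signed-rank critical values at alpha = 0.05: reject the
## null when T = min(R+, R-) is <= the tabled value. NA below n = 6 (no
## rejection is possible). The same numbers fall out of the exact null
## distribution (see exact_signed_rank_threshold), which extends the table to
## any alpha.
WILCOXON_CRIT_05 <- c(`6` = 0, `7` = 2, `8` = 3, `9` = 5, `10` = 8,
                      `11` = 10, `12` = 13, `13` = 17, `14` = 21, `15` = 25,
                      `16` = 29, `17` = 34, `18` = 40, `19` = 46, `20` = 52,
                      `21` = 58, `22` = 65, `23` = 73, `24` = 81, `25` = 89)

## Largest c with 2 * P(R+ <= c) <= alpha under the exact null for untied
## ranks 1..n; -1 when even c = 0 is not extreme enough (never reject).
exact_signed_rank_threshold <- function(n, alpha) {
  if (n < 1L) return(-1)
  cand <- 0:(n * (n + 1) / 4)
  ok <- 2 * stats::psignrank(cand, n) <= alpha
  if (!any(ok)) -1 else max(cand[ok])
}

## Exact two-sided p-value of T by dynamic programming over the (possibly
## tied, half-integer) ranks: distribution of R+ over all 2^n sign
## assignments, computed as a polynomial product over doubled ranks.
exact_signed_rank_p <- function(ranks, T_stat) {
  r2 <- as.integer(round(2 * ranks))
  dist <- c(1)                                # dist[s+1] = #assignments with 2*R+ = s
  for (r in r2)
    dist <- c(dist, rep(0, r)) + c(rep(0, r), dist)   # multiply by (1 + x^r)
  dist <- dist / sum(dist)
  total <- sum(r2)
  s <- seq_along(dist) - 1L
  lo <- sum(dist[pmin(s, total - s) <= round(2 * T_stat)])
  min(1, lo)
}

#' Paired Wilcoxon signed-rank comparison of two algorithms
#'
#' Follows the small-sample tabulated procedure: zero differences are
#' dropped, absolute differences are ranked ascending with ties receiving
#' averaged ranks, signs are reattached, and the positive and negative rank
#' sums `R+` and `R-` are formed. The test statistic is `T = min(R+, R-)`,
#' rejected when it is at or below the critical value. With
#' `follow_paper = TRUE` (default) the critical value at `n_effective = 6`,
#' `alpha = 0.05` is 2 — the convention used in the study this package
#' follows; the standard two-sided table gives 0 there, and both decisions
#' are reported.
#'
#' @param a,b Equal-length metric vectors for the two algorithms.
#' @param alpha Significance level.
#' @param follow_paper Use the threshold-2 convention at `n_effective = 6`.
#' @param name_a,name_b Algorithm names used for the `selected` field.
#' @return An object of class `wilcoxon_result` with fields `R_plus`,
#'   `R_minus`, `T_stat`, `n_effective`, `threshold`, `threshold_standard`,
#'   `reject`, `reject_standard`, `p_exact` and `selected` (the winning
#'   algorithm name, or `NA` when the null is retained).
#' @export
wilcoxon_signed_rank <- function(a, b, alpha = 0.05, follow_paper = TRUE,
                                 name_a = "a", name_b = "b") {
  if (length(a) != length(b)) stop("unequal lengths", call. = FALSE)
  if (length(a) < 1L) stop("empty input", call. = FALSE)
  d <- a - b
  d <- d[d != 0]
  n_eff <- length(d)
  if (n_eff == 0L) {
    return(structure(list(R_plus = 0, R_minus = 0, T_stat = 0,
                          n_effective = 0L, threshold = NA_real_,
                          threshold_standard = NA_real_, reject = FALSE,
                          reject_standard = FALSE, p_exact = 1,
                          selected = NA_character_, alpha = alpha,
                          follow_paper = follow_paper,
                          all_zero = TRUE),
                     class = "wilcoxon_result"))
  }
  rk <- rank(abs(d), ties.method = "average")
  R_plus <- sum(rk[d > 0]); R_minus <- sum(rk[d < 0])
  T_stat <- min(R_plus, R_minus)
  thr_std <- if (alpha == 0.05 && n_eff >= 6L && n_eff <= 25L)
    unname(WILCOXON_CRIT_05[as.character(n_eff)])
  else exact_signed_rank_threshold(n_eff, alpha)
  thr <- thr_std
  if (follow_paper && n_eff == 6L && alpha == 0.05) thr <- 2
  reject <- !is.na(thr) && thr >= 0 && T_stat <= thr
  reject_std <- !is.na(thr_std) && thr_std >= 0 && T_stat <= thr_std
  selected <- if (reject) { if (R_plus >= R_minus) name_a else name_b
  } else NA_character_
  structure(list(R_plus = R_plus, R_minus = R_minus, T_stat = T_stat,
                 n_effective = n_eff, threshold = thr,
                 threshold_standard = thr_std, reject = reject,
                 reject_standard = reject_std,
                 p_exact = exact_signed_rank_p(rk, T_stat),
                 selected = selected, alpha = alpha,
                 follow_paper = follow_paper, all_zero = FALSE),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat("<wilcoxon_result> R+ =", x$R_plus, " R- =", x$R_minus,
      " T =", x$T_stat, " n =", x$n_effective, "\n")
  cat("  threshold =", x$threshold, "-> ",
      if (x$reject) "Rejected" else "Retained",
      if (!is.na(x$selected)) paste0("; selected = ", x$selected) else "", "\n")
  invisible(x)
}

#' Average ranks of algorithms over a results table
#'
#' Within each row (evaluation index) the algorithms are ranked, best = 1,
#' with tied values receiving averaged ranks; the per-algorithm column means
#' are returned. With `higher_is_better = TRUE` (the metric convention) the
#' largest value ranks first.
#'
#' @param tbl Numeric matrix, N index rows by k algorithm columns.
#' @param higher_is_better Rank descending values first.
#' @return Named numeric vector of average ranks, one per column.
#' @export
average_ranks <- function(tbl, higher_is_better = TRUE) {
  tbl <- as.matrix(tbl)
  rk <- rank_matrix(tbl, higher_is_better)
  colMeans(rk)
}

rank_matrix <- function(tbl, higher_is_better = TRUE) {
  sgn <- if (higher_is_better) -1 else 1
  t(apply(tbl, 1L, function(v) rank(sgn * v, ties.method = "average")))
}

#' Friedman statistics from average ranks
#'
#' The rank-based chi-square statistic
#' `chi2_F = 12N / (k(k+1)) * (sum(R_j^2) - k(k+1)^2 / 4)` and its
#' F-distributed transformation
#' `F_F = (N-1) chi2_F / (N(k-1) - chi2_F)`. When `digits` is given, the
#' average ranks are rounded before the chi-square and the chi-square is
#' rounded before the transformation — the arithmetic used for the published
#' worked example this package reproduces (see the vignette).
#'
#' @param avg_ranks Average rank per algorithm (length k).
#' @param N Number of evaluation indexes (rows ranked).
#' @param k Number of algorithms; defaults to `length(avg_ranks)`.
#' @param digits Optional rounding of intermediate values.
#' @return List with `chi2`, `FF` (`Inf` when the chi-square saturates at
#'   `N(k-1)`).
#' @export
friedman_from_ranks <- function(avg_ranks, N, k = length(avg_ranks),
                                digits = NULL) {
  R <- avg_ranks
  if (!is.null(digits)) R <- round(R, digits)
  chi2 <- 12 * N / (k * (k + 1)) * (sum(R^2) - k * (k + 1)^2 / 4)
  if (!is.null(digits)) chi2 <- round(chi2, digits)
  denom <- N * (k - 1) - chi2
  FF <- if (denom <= 0) Inf else (N - 1) * chi2 / denom
  list(chi2 = chi2, FF = FF)
}

#' Friedman test over a metric-by-algorithm results table
#'
#' Ranks each of the N index rows over the k algorithm columns (ties
#' averaged), averages ranks per algorithm, and computes the Friedman
#' chi-square and its F transformation (see [friedman_from_ranks()]). The
#' null of no difference among algorithms is rejected when `F_F` exceeds the
#' F critical value. Two critical values are reported: the exact one at
#' degrees of freedom `(k-1, (k-1)(N-1))` and the `(k, k(N-1))` convention
#' used in the study this package follows; both decisions are returned.
#'
#' @param tbl Numeric matrix (or [results_table()]), N rows x k columns,
#'   k >= 2, N >= 2.
#' @param alpha Significance level.
#' @param higher_is_better Rank descending values first.
#' @param digits Optional intermediate rounding (see
#'   [friedman_from_ranks()]).
#' @return An object of class `friedman_result`.
#' @export
friedman_test <- function(tbl, alpha = 0.05, higher_is_better = TRUE,
                          digits = NULL) {
  tbl <- as.matrix(tbl)
  N <- nrow(tbl); k <- ncol(tbl)
  if (N < 2L || k < 2L) stop("need N >= 2 and k >= 2", call. = FALSE)
  if (anyNA(tbl)) stop("missing cells", call. = FALSE)
  rk <- rank_matrix(tbl, higher_is_better)
  avg <- colMeans(rk)
  fr <- friedman_from_ranks(avg, N, k, digits = digits)
  df1 <- k - 1L; df2 <- (k - 1L) * (N - 1L)
  crit_exact <- stats::qf(1 - alpha, df1, df2)
  crit_paper <- stats::qf(1 - alpha, k, k * (N - 1L))
  structure(list(rank_matrix = rk, avg_ranks = avg, chi2 = fr$chi2,
                 FF = fr$FF, N = N, k = k, df1 = df1, df2 = df2,
                 critical_exact = crit_exact, critical_paper = crit_paper,
                 reject_exact = fr$FF > crit_exact,
                 reject_paper = fr$FF > crit_paper, alpha = alpha),
            class = "friedman_result")
}

#' @export
print.friedman_result <- function(x, ...) {
  cat("<friedman_result> N =", x$N, " k =", x$k, "\n")
  cat("  chi2_F =", round(x$chi2, 4), "  F_F =", round(x$FF, 4), "\n")
  cat("  F crit (df ", x$df1, ",", x$df2, ") = ", round(x$critical_exact, 3),
      " -> ", if (x$reject_exact) "Rejected" else "Retained", "\n", sep = "")
  cat("  F crit (df ", x$k, ",", x$k * (x$N - 1L), ") = ",
      round(x$critical_paper, 3), " -> ",
      if (x$reject_paper) "Rejected" else "Retained", "\n", sep = "")
  invisible(x)
}
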