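# The two statistical instruments of the stability analysis: unpaired
# Mann-Whitney U tests across ROI-size pairs (Bonferroni-corrected within
# the three pairs), and the overall concordance correlation coefficient
# (OCCC, Barnhart's generalization of Lin's CCC) with the >= 0.90
# excellent-agreement rule.

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. The null distribution is exact (by enumeration
#' of rank assignments) when both samples have at most 8 observations and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity correction is used. The U statistic is reported for the first
#' sample.
#'
#' @param x,y Numeric samples (non-empty).
#' @param exact Override the exact/approximate switch (logical), or `NULL`
#'   for the default rule.
#' @return List with `U`, `p` and `method` (`"exact"` or `"normal"`).
#' @examples
#' mwu_test(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mwu_test <- function(x, y, exact = NULL) {
  if (length(x) == 0L || length(y) == 0L) .stopf("mwu_test needs non-empty samples")
  ties <- anyDuplicated(c(x, y)) > 0L
  if (is.null(exact)) exact <- length(x) <= 8L && length(y) <= 8L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = unname(wt$p.value),
       method = if (exact && !ties) "exact" else "normal")
}

#' Pairwise ROI-size tests with Bonferroni correction
#'
#' Tests all three size pairs (10 vs 20, 10 vs 30, 20 vs 30 mm) with the
#' unpaired two-sided Mann-Whitney U test and multiplies each p-value by
#' the family size (3, the number of size pairs; configurable), capped at 1.
#' The test is applied unpaired even though the size groups share subjects,
#' matching the study design being emulated.
#'
#' @param by_size Named list of per-subject value vectors, names are the
#'   diameters (all of `sizes` must be present; equal lengths, subjects in
#'   the same order).
#' @param alpha Significance level (default 0.05).
#' @param sizes The diameters to test pairwise.
#' @param family Bonferroni family size (default: the number of pairs).
#' @return Data frame with one row per pair: `size_a`, `size_b`, `U`,
#'   `p_raw`, `p_adj`, `significant`.
#' @export
pairwise_size_tests <- function(by_size, alpha = 0.05,
                                sizes = c(10, 20, 30), family = NULL) {
  key <- as.character(sizes)
  missing <- setdiff(key, names(by_size))
  if (length(missing) > 0L)
    .stopf("missing size group(s): %s mm", paste(missing, collapse = ", "))
  pairs <- utils::combn(key, 2L)
  if (is.null(family)) family <- ncol(pairs)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    t <- mwu_test(by_size[[a]], by_size[[b]])
    data.frame(size_a = as.numeric(a), size_b = as.numeric(b),
               U = t$U, p_raw = t$p,
               p_adj = min(1, family * t$p))
  })
  out <- do.call(rbind, res)
  out$significant <- out$p_adj < alpha
  out
}

#' Overall concordance correlation coefficient (OCCC)
#'
#' Barnhart's overall CCC over J subject-matched measurement groups, in
#' moment form:
#' `occc = 2 * sum_{j<k} s_jk / ((J-1) * sum_j s_j^2 + sum_{j<k} (m_j - m_k)^2)`
#' where `m_j`, `s_j^2` and `s_jk` are per-group means, variances and
#' covariances. With `divisor = "n"` (the default, Lin's original
#' convention) moments use 1/n divisors; `"n-1"` is available since the
#' choice slightly moves the estimate at small n. For J = 2 the OCCC equals
#' Lin's CCC. Values lie in [-1, 1]: 1 is complete agreement, -1 reverse
#' agreement.
#'
#' @param groups List of J >= 2 equal-length numeric vectors (same
#'   subjects, same order), or a numeric matrix with one column per group.
#' @param threshold Excellent-agreement threshold (default 0.90).
#' @param divisor `"n"` or `"n-1"` moment divisors.
#' @return An object of class `occc_result`: list with `occc`, `excellent`,
#'   `J`, `n` and `degenerate`. When every group is constant and equal the
#'   estimator is 0/0; the result is flagged `degenerate = TRUE` with
#'   `occc = NA` and `excellent = FALSE`.
#' @examples
#' x <- rnorm(20)
#' occc(list(x, x, x))$occc   # exactly 1
#' @export
occc <- function(groups, threshold = 0.90, divisor = c("n", "n-1")) {
  divisor <- match.arg(divisor)
  X <- if (is.matrix(groups)) groups else {
    if (length(unique(lengths(groups))) != 1L)
      .stopf("all groups must have the same length")
    do.call(cbind, groups)
  }
  J <- ncol(X); n <- nrow(X)
  if (J < 2L) .stopf("occc needs at least 2 groups")
  if (n < 2L) .stopf("occc needs at least 2 matched observations")
  m <- colMeans(X)
  S <- stats::cov(X)
  if (divisor == "n") S <- S * (n - 1) / n
  ut <- upper.tri(S)
  num <- 2 * sum(S[ut])
  den <- (J - 1) * sum(diag(S)) + sum(outer(m, m, `-`)[ut]^2)
  if (den <= .Machine$double.eps * max(1, sum(m^2))) {
    return(structure(list(occc = NA_real_, excellent = FALSE, J = J, n = n,
                          degenerate = TRUE, threshold = threshold),
                     class = "occc_result"))
  }
  val <- num / den
  val <- max(-1, min(1, val))
  structure(list(occc = val, excellent = val >= threshold, J = J, n = n,
                 degenerate = FALSE, threshold = threshold),
            class = "occc_result")
}

#' @export
print.occc_result <- function(x, ...) {
  if (x$degenerate)
    cat("<occc> degenerate (all groups constant and equal)\n")
  else
    cat(sprintf("<occc> %.4f over J = %d groups, n = %d (%sexcellent at >= %.2f)\n",
                x$occc, x$J, x$n, if (x$excellent) "" else "not ", x$threshold))
  invisible(x)
}

#' OCCC over both ROI-size subsets
#'
#' Computes the OCCC twice: over all three diameters (10, 20, 30 mm) and
#' over the two largest (20, 30 mm). The second subset probes whether the
#' smallest ROI alone degrades agreement.
#'
#' @param by_size Named list of per-subject value vectors keyed by diameter;
#'   must contain all of `sizes`.
#' @param sizes The full diameter set (default `c(10, 20, 30)`); the second
#'   subset drops the smallest.
#' @param threshold Excellent-agreement threshold.
#' @param divisor Passed to [occc()].
#' @return List with elements `all` (OCCC over all sizes) and `large`
#'   (OCCC over the subset without the smallest size), each an
#'   `occc_result` tagged with its `sizes`.
#' @export
occc_both_subsets <- function(by_size, sizes = c(10, 20, 30),
                              threshold = 0.90, divisor = "n") {
  key <- as.character(sort(sizes))
  missing <- setdiff(key, names(by_size))
  if (length(missing) > 0L)
    .stopf("missing size group(s): %s mm", paste(missing, collapse = ", "))
  sub <- key[-1L]
  r_all <- occc(by_size[key], threshold = threshold, divisor = divisor)
  r_lrg <- occc(by_size[sub], threshold = threshold, divisor = divisor)
  r_all$sizes <- as.numeric(key)
  r_lrg$sizes <- as.numeric(sub)
  list(all = r_all, large = r_lrg)
}
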