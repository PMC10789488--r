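#' Spearman rank correlation
#'
#' Pearson correlation of average ranks, computed on pairwise-complete
#' observations. Returns `NA` when either vector is constant after deletion
#' (the correlation is undefined) or fewer than 3 complete pairs remain.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A scalar in \[-1, 1\], or `NA`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Partial Spearman correlation
#'
#' Rank-transforms all three vectors (average ranks for ties), then correlates
#' the OLS residuals of the x-ranks and y-ranks on the covariate ranks.
#' Degenerate residuals (zero variance, e.g. `y` identical to the covariate)
#' yield `NA`, never a silent zero.
#'
#' @param x,y Numeric vectors.
#' @param covariate Numeric vector to partial out.
#' @return A scalar partial correlation, or `NA`.
#' @export
partial_spearman <- function(x, y, covariate) {
  stopifnot(length(x) == length(y), length(x) == length(covariate))
  ok <- is.finite(x) & is.finite(y) & is.finite(covariate)
  if (sum(ok) < 4L) return(NA_real_)
  rx <- rank(x[ok]); ry <- rank(y[ok]); rc <- rank(covariate[ok])
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  ex <- if (stats::sd(rc) == 0) rx - mean(rx) else stats::lm.fit(cbind(1, rc), rx)$residuals
  ey <- if (stats::sd(rc) == 0) ry - mean(ry) else stats::lm.fit(cbind(1, rc), ry)$residuals
  # residuals that vanish up to floating noise (e.g. y identical to the
  # covariate) leave the partial correlation undefined
  if (stats::sd(ex) <= 1e-10 * stats::sd(rx) || stats::sd(ey) <= 1e-10 * stats::sd(ry))
    return(NA_real_)
  stats::cor(ex, ey)
}

#' Fisher z-transform of a correlation coefficient
#'
#' `atanh` after clipping to |r| <= 1 - 1e-6, so perfectly (anti)correlated
#' inputs stay finite. `fisher_z_inv` is the plain `tanh` inverse.
#'
#' @param r Correlation coefficient(s), |r| <= 1.
#' @return Transformed value(s); `NA` propagates.
#' @export
fisher_z <- function(r) {
  bad <- !is.na(r) & abs(r) > 1
  if (any(bad)) stop("fisher_z: |r| > 1")
  atanh(pmin(pmax(r, -(1 - 1e-6)), 1 - 1e-6))
}

#' @rdname fisher_z
#' @param z Fisher z value(s).
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values across a family of tests.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (`NA` allowed).
#' @return q-values, same length and order as the input.
#' @export
bh_fdr <- function(p_values) {
  pv <- p_values[!is.na(p_values)]
  if (length(pv) && (any(pv < 0) || any(pv > 1))) stop("bh_fdr: p-values outside [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Exact permutation p-value
#'
#' The add-one convention: p = (1 + #\{null at least as extreme as observed\})
#' / (1 + n_perm), so p is never 0 and never below 1/(n_perm + 1).
#'
#' @param observed Observed statistic.
#' @param null_draws Numeric vector of permutation-null statistics.
#' @param sidedness `"two.sided"` (compares |values|), `"greater"` or `"less"`.
#' @return p-value in \[1/(n_perm+1), 1\].
#' @export
exact_perm_pvalue <- function(observed, null_draws,
                              sidedness = c("two.sided", "greater", "less")) {
  sidedness <- match.arg(sidedness)
  n_perm <- length(null_draws)
  stopifnot(n_perm >= 1L)
  hits <- switch(sidedness,
    two.sided = sum(abs(null_draws) >= abs(observed)),
    greater   = sum(null_draws >= observed),
    less      = sum(null_draws <= observed))
  (1 + hits) / (1 + n_perm)
}

#' Two-sample t-test from printed summary statistics
#'
#' Reconstructs the group-comparison t statistic from per-group mean, SD and N
#' as printed in a demographics table. The default pools the two variances
#' (df = n1 + n2 - 2); `welch = TRUE` uses the Welch-Satterthwaite form.
#'
#' @param m1,s1,n1 Mean, SD, N of group 1.
#' @param m2,s2,n2 Mean, SD, N of group 2.
#' @param welch Use Welch's unequal-variance t instead of pooling.
#' @return A list with `t` and `df`. If both SDs are zero: `t = 0` for equal
#'   means, `t = Inf` (signed) otherwise, flagged with `degenerate = TRUE`.
#' @export
pooled_t_from_summary <- function(m1, s1, n1, m2, s2, n2, welch = FALSE) {
  stopifnot(n1 >= 2L, n2 >= 2L, s1 >= 0, s2 >= 0)
  if (s1 == 0 && s2 == 0) {
    tval <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
    return(list(t = tval, df = n1 + n2 - 2, degenerate = TRUE))
  }
  if (welch) {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(t = (m1 - m2) / se, df = df, degenerate = FALSE)
}

#' Pearson chi-square for a 2x2 table
#'
#' No continuity correction (the convention that reproduces printed
#' sex-distribution statistics from cohort tables).
#'
#' @param a,b,c,d Cell counts, rows = groups, columns = categories.
#' @return The chi-square statistic (df = 1).
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  n <- a + b + c + d
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    stop("chi_square_2x2: zero margin")
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

#' ROC area under the curve by pair counting
#'
#' AUC = fraction of (positive, negative) pairs with positive score >
#' negative score, ties counted one half -- the Mann-Whitney U identity,
#' computed through the rank-sum form so ties are handled exactly.
#'
#' @param positives,negatives Numeric score vectors (both nonempty).
#' @return AUC in \[0, 1\].
#' @export
auc_mann_whitney <- function(positives, negatives) {
  stopifnot(length(positives) >= 1L, length(negatives) >= 1L,
            all(is.finite(positives)), all(is.finite(negatives)))
  n1 <- length(positives); n2 <- length(negatives)
  r <- rank(c(positives, negatives))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' ROC curve points
#'
#' False-positive / true-positive rates at every distinct score threshold,
#' ordered from (0,0) to (1,1).
#'
#' @param positives,negatives Numeric score vectors.
#' @return Data frame with columns `fpr` and `tpr`.
#' @export
roc_points <- function(positives, negatives) {
  thr <- sort(unique(c(positives, negatives, Inf)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(positives >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(negatives >= t), numeric(1))
  data.frame(fpr = fpr, tpr = tpr)
}
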