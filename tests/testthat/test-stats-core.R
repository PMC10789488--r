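test_that("spearman_rho matches the average-rank Pearson definition", {
  expect_equal(spearman_rho(1:7, c(2, 4, 9, 11, 30, 40, 41)), 1)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_true(is.na(spearman_rho(rep(1, 5), 1:5)))
  set.seed(42)
  for (i in 1:300) {
    n <- sample(4:15, 1)
    x <- sample(1:6, n, replace = TRUE)   # heavy ties
    y <- sample(1:6, n, replace = TRUE)
    ox <- spearman_oracle(x, y)
    if (is.nan(ox)) next
    expect_equal(spearman_rho(x, y), ox, tolerance = 1e-12)
  }
})

test_that("partial_spearman equals both rank-residual and recursive-formula oracles", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(6:20, 1)
    x <- rnorm(n); y <- rnorm(n); z <- rnorm(n)
    got <- partial_spearman(x, y, z)
    expect_equal(got, partial_spearman_residual_oracle(x, y, z), tolerance = 1e-10)
    expect_equal(got, partial_spearman_recursive_oracle(x, y, z), tolerance = 1e-10)
  }
  # independent covariate at large n: partial ~ plain
  set.seed(8)
  x <- rnorm(500); y <- x + rnorm(500); z <- rnorm(500)
  expect_equal(partial_spearman(x, y, z), spearman_rho(x, y), tolerance = 0.05)
  # y exactly the covariate -> degenerate residuals -> missing
  expect_true(is.na(partial_spearman(rnorm(10), 1:10, 1:10)))
})

test_that("fisher transform is atanh with clipping and exact inverse", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  expect_true(is.finite(fisher_z(1)))
  expect_error(fisher_z(1.2), "\\|r\\|")
  r <- seq(-0.99, 0.99, by = 0.11)
  expect_equal(fisher_z_inv(fisher_z(r)), r, tolerance = 1e-9)
})

test_that("bh_fdr matches the exhaustive step-up oracle and is order-invariant", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.01, 0.04, 0.03, 0.02)
  expect_equal(bh_fdr(p), bh_oracle(p))
  set.seed(11)
  for (i in 1:200) {
    p <- runif(sample(1:20, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), q[perm])
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "outside")
})

test_that("exact permutation p-values follow the add-one convention", {
  expect_equal(exact_perm_pvalue(10, rnorm(99), "greater"), 0.01)
  set.seed(3)
  expect_gt(exact_perm_pvalue(0, rnorm(999), "two.sided"), 0.9)
  for (i in 1:50) {
    nd <- rnorm(sample(1:50, 1))
    p <- exact_perm_pvalue(rnorm(1), nd, "two.sided")
    expect_gte(p, 1 / (length(nd) + 1))
    expect_lte(p, 1)
  }
})

test_that("pooled-variance t reproduces printed cohort-table statistics", {
  # age row
  expect_equal(pooled_t_from_summary(61.5, 10.0, 52, 63.6, 11.9, 22)$t,
               -0.78, tolerance = 0.01)
  # apathy scale row
  expect_equal(pooled_t_from_summary(32.7, 11.0, 35, 9.50, 5.26, 4)$t,
               4.13, tolerance = 0.01)
  # frontal-systems total frequency row
  expect_equal(pooled_t_from_summary(72.7, 16.1, 34, 38.8, 12.3, 5)$t,
               4.49, tolerance = 0.01)
  eq <- pooled_t_from_summary(5, 2, 10, 5, 2, 10)
  expect_equal(eq$t, 0)
  expect_equal(eq$df, 18)
  deg <- pooled_t_from_summary(3, 0, 5, 1, 0, 5)
  expect_true(deg$degenerate && is.infinite(deg$t))
  expect_equal(pooled_t_from_summary(3, 0, 5, 3, 0, 5)$t, 0)
  # Welch variant differs when variances are unequal
  expect_false(isTRUE(all.equal(
    pooled_t_from_summary(32.7, 11.0, 35, 9.50, 5.26, 4, welch = TRUE)$t, 4.13,
    tolerance = 0.01)))
})

test_that("2x2 chi-square reproduces the printed sex-distribution statistic", {
  expect_equal(chi_square_2x2(38, 14, 9, 13), 6.90, tolerance = 0.01)
  expect_equal(chi_square_2x2(10, 10, 10, 10), 0)
  expect_equal(chi_square_2x2(5, 0, 0, 5), 10)
  expect_error(chi_square_2x2(5, 5, 0, 0), "margin")
})

test_that("AUC equals the Mann-Whitney pair-counting statistic on every input", {
  expect_equal(auc_mann_whitney(1, 1), 0.5)
  expect_equal(auc_mann_whitney(c(5, 6), c(1, 2)), 1)
  expect_equal(auc_mann_whitney(c(0.9, 0.8), c(0.7, 0.85)), 0.75)
  set.seed(21)
  for (i in 1:200) {
    pos <- sample(1:8, sample(1:10, 1), replace = TRUE)
    neg <- sample(1:8, sample(1:10, 1), replace = TRUE)
    expect_equal(auc_mann_whitney(pos, neg), auc_pairs_oracle(pos, neg),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  pos <- rnorm(20, 0.4); neg <- rnorm(15)
  got <- auc_mann_whitney(pos, neg)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = rep(c(1, 0), c(20, 15)), predictor = c(pos, neg),
    direction = "<", quiet = TRUE)))
  expect_equal(got, ref, tolerance = 1e-12)
})
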