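test_that("z-scoring against controls matches an explicit per-region loop", {
  set.seed(1)
  ctl <- matrix(rnorm(8 * 12), 8)
  pat <- rnorm(12)
  z <- zscore_vs_controls(pat, ctl)
  for (r in 1:12)
    expect_equal(unname(z[r]), (pat[r] - mean(ctl[, r])) / sd(ctl[, r]),
                 tolerance = 1e-12)
  expect_equal(unname(zscore_vs_controls(colMeans(ctl), ctl)), rep(0, 12))
  one_sd <- colMeans(ctl) + apply(ctl, 2, sd)
  expect_equal(unname(zscore_vs_controls(one_sd, ctl)), rep(1, 12))
  # zero control SD -> missing
  ctl2 <- ctl; ctl2[, 3] <- 5
  expect_true(is.na(zscore_vs_controls(pat, ctl2)[3]))
  expect_error(zscore_vs_controls(pat, ctl[1, , drop = FALSE]), ">= 2")
})

test_that("leave-one-out z-maps equal explicit hold-one-out recomputation", {
  set.seed(2)
  ctl <- matrix(rnorm(6 * 10), 6)
  loo <- loo_control_zscores(ctl)
  expect_equal(dim(loo), dim(ctl))
  for (i in 1:6)
    expect_equal(loo[i, ], zscore_vs_controls(ctl[i, ], ctl[-i, ]),
                 tolerance = 1e-12)
  # identical controls: SD zero -> all missing per the missing rule
  same <- matrix(1, 4, 10) * rep(1:10, each = 4)
  expect_true(all(is.na(loo_control_zscores(same))))
  expect_error(loo_control_zscores(ctl[1:2, ]), ">= 3")
})

test_that("coloc_profile is a clipped Fisher-z Spearman with GM partialling", {
  set.seed(3)
  tpl <- rnorm(50)
  # zmap equal to the template's ranks -> rho = 1 -> clipped large z
  expect_equal(coloc_profile(rank(tpl), tpl), atanh(1 - 1e-6))
  # independent at n = 200 -> near zero
  expect_lt(abs(coloc_profile(rnorm(200), rnorm(200))), 0.2)
  # GM vector independent of both: partial ~ plain, and matches the
  # rank-residual regression oracle exactly
  z <- rnorm(200); t2 <- 0.5 * z + rnorm(200); gm <- rnorm(200)
  plain <- coloc_profile(z, t2)
  adj <- coloc_profile(z, t2, gm, adjust_gm = TRUE)
  expect_equal(adj, plain, tolerance = 0.1)
  expect_equal(adj, atanh(partial_spearman_residual_oracle(z, t2, gm)),
               tolerance = 1e-10)
  expect_error(coloc_profile(c(1, 2, 3), c(1, 2, 3)), "4")
  # monotone invariance of the unadjusted coefficient
  expect_equal(coloc_profile(exp(z), t2^3 + 5 * t2), coloc_profile(exp(z), t2),
               tolerance = 1e-12)
})

test_that("compiled profile engine agrees with the pure-R reference path", {
  set.seed(4)
  n_pat <- 9; n_ctl <- 7; n_reg <- 40; n_tpl <- 5
  pat <- matrix(rnorm(n_pat * n_reg), n_pat)
  ctl <- matrix(rnorm(n_ctl * n_reg), n_ctl)
  tpl <- matrix(rnorm(n_reg * n_tpl), n_reg)
  gm <- runif(n_reg)
  for (adj in c(FALSE, TRUE)) {
    fast <- coloc_profiles(pat, ctl, tpl, gm_rv = gm, adjust_gm = adj)
    zm <- t(apply(pat, 1, zscore_vs_controls, control_rvs = ctl))
    slow <- neurocoloc:::coloc_profiles_r(zm, tpl, if (adj) gm else NULL, adj)
    expect_equal(unname(fast), unname(slow), tolerance = 1e-10)
  }
  # observed statistic of the permutation engine equals the R fallback
  X <- rbind(pat, ctl)
  is_pat <- rep(c(TRUE, FALSE), c(n_pat, n_ctl))
  for (adj in c(FALSE, TRUE)) {
    eng <- neurocoloc:::.coloc_perm_engine(X, is_pat, tpl,
                                           if (adj) gm else numeric(0), 100L)
    set.seed(1)
    rr <- neurocoloc:::coloc_perm_r(X, is_pat, tpl, if (adj) gm else NULL,
                                    adj, 3)
    expect_equal(as.numeric(eng$observed), unname(rr$observed), tolerance = 1e-10)
  }
})

test_that("group test: p-value floor, group-size conservation, FDR monotonicity", {
  set.seed(5)
  n_reg <- 40
  tpl <- matrix(rnorm(n_reg * 3), n_reg)
  ctl <- matrix(rnorm(10 * n_reg), 10)
  # patients strongly anti-aligned with template 1
  pat <- t(vapply(1:12, function(i) -3 * tpl[, 1] + rnorm(n_reg, sd = 0.3),
                  numeric(n_reg)))
  res <- coloc_group_test(pat, ctl, tpl, n_perm = 199, seed = 6)
  expect_equal(res$table$p[1], 1 / 200)
  expect_lt(res$table$mean_r[1], -0.5)
  expect_true(all(res$table$q >= res$table$p - 1e-15))
  expect_equal(res$table$q, bh_oracle(res$table$p))
  expect_equal(dim(res$profiles), c(12L, 3L))
  # mean_r is the back-transformed mean Fisher z of the observed profiles
  expect_equal(res$table$mean_z, unname(colMeans(res$profiles)), tolerance = 1e-10)
  expect_equal(res$table$mean_r, tanh(res$table$mean_z))
})

test_that("missing regions fall back to pairwise deletion, never imputation", {
  set.seed(6)
  n_reg <- 30
  tpl <- matrix(rnorm(n_reg * 2), n_reg)
  ctl <- matrix(rnorm(8 * n_reg), 8)
  pat <- matrix(rnorm(6 * n_reg), 6)
  pat[2, 5] <- NA  # one missing region for one patient
  res <- coloc_group_test(pat, ctl, tpl, n_perm = 100, seed = 7)
  # the affected profile equals the profile computed on the reduced region set
  zm <- zscore_vs_controls(pat[2, ], ctl)
  keep <- !is.na(zm)
  expect_equal(unname(res$profiles[2, 1]),
               atanh(spearman_rho(zm[keep], tpl[keep, 1])), tolerance = 1e-10)
})

test_that("ROC output satisfies the AUC/pair-count identity and orientation flag", {
  expect_equal(coloc_roc(matrix(c(0.9, 0.8)), matrix(c(0.7, 0.85)))$auc, 0.75)
  set.seed(7)
  pat <- matrix(rnorm(20), 20, 1); ctl <- matrix(rnorm(15), 15, 1)
  r <- coloc_roc(pat, ctl)
  expect_equal(r$auc, auc_pairs_oracle(pat[, 1], ctl[, 1]))
  expect_gte(r$auc_oriented, 0.5)
  # perfectly separated
  r2 <- coloc_roc(matrix(1:5), matrix(-(1:5)))
  expect_equal(r2$auc, 1)
  # identical distributions -> AUC 0.5 in expectation (exact here by symmetry)
  r3 <- coloc_roc(matrix(1:4), matrix(1:4))
  expect_equal(r3$auc, 0.5)
  expect_error(coloc_roc(matrix(numeric(0), 0, 1), ctl), "empty")
  # curve rises from (0,0) to (1,1)
  cv <- r$curve[[1]]
  expect_equal(cv$fpr[1], 0); expect_equal(cv$tpr[1], 0)
  expect_equal(cv$fpr[nrow(cv)], 1); expect_equal(cv$tpr[nrow(cv)], 1)
  expect_true(all(diff(cv$fpr) >= 0) && all(diff(cv$tpr) >= 0))
})
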