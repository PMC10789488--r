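test_that("atlas generation partitions a connected mask deterministically", {
  atl <- generate_atlas(c(8, 8, 8), 4, seed = 1)
  mask <- atl$labels > 0
  expect_equal(sort(unique(as.integer(atl$labels[mask]))), 1:4)
  expect_true(all(atl$labels[!mask] == 0))
  expect_true(all(tabulate(atl$labels[mask], 4) > 0))
  atl2 <- generate_atlas(c(8, 8, 8), 4, seed = 1)
  expect_identical(atl$labels, atl2$labels)
  expect_false(identical(generate_atlas(c(8, 8, 8), 4, seed = 2)$labels,
                         atl$labels))
  expect_error(generate_atlas(c(2, 2, 2), 100, seed = 1), "exceeds")
})

test_that("template maps are nonnegative, non-degenerate, and decorrelated below the cap", {
  atl <- generate_atlas(c(10, 10, 10), 30, seed = 2)
  tpl <- generate_template_maps(atl, 6, smoothness = 1.5, seed = 3, cap = 0.3)
  for (m in tpl$maps) expect_true(all(m$values[m$mask] >= 0))
  expect_true(all(apply(tpl$regional, 2, var) > 0))
  cm <- abs(cor(tpl$regional, method = "spearman")); diag(cm) <- 0
  expect_lte(max(cm), 0.3)
  # smoothness 0: voxelwise independent noise has near-zero lag-1 correlation
  tpl0 <- generate_template_maps(atl, 2, smoothness = 0, seed = 4)
  v <- tpl0$maps[[1]]$values[, 5, 5]
  expect_lt(abs(cor(v[1:9], v[2:10], use = "complete.obs")), 0.9)
  # unattainable cap errors, naming the cap
  expect_error(generate_template_maps(atl, 40, seed = 5, cap = 0.01,
                                      max_retries = 3), "0.01")
})

test_that("cohort generation is deterministic and honors the planted model", {
  fx <- tiny_cohort(n_pat = 6, n_ctl = 4, beta = 0.5, seed = 10)
  fx2 <- tiny_cohort(n_pat = 6, n_ctl = 4, beta = 0.5, seed = 10)
  expect_identical(fx$cohort$subjects, fx2$cohort$subjects)
  for (i in seq_along(fx$cohort$maps))
    expect_identical(fx$cohort$maps[[i]]$values, fx2$cohort$maps[[i]]$values)
  expect_equal(fx$cohort$ground_truth$beta, 0.5)
  expect_equal(fx$cohort$ground_truth$planted_template_index, 1)
  # demographics resemble the configured distributions
  big <- synthetic_config(grid_shape = c(8, 8, 8), n_regions = 10,
                          n_templates = 2, n_patients = 200, n_controls = 100,
                          planted_template_index = NA, seed = 11)
  atl <- generate_atlas(c(8, 8, 8), 10, seed = 11)
  tpl <- generate_template_maps(atl, 2, seed = 12)
  coh <- generate_cohort(atl, tpl, big)
  pat <- coh$subjects[coh$subjects$group == "patient", ]
  ctl <- coh$subjects[coh$subjects$group == "control", ]
  expect_equal(mean(pat$age), 61.5, tolerance = 3)
  expect_equal(mean(ctl$age), 63.6, tolerance = 4)
  expect_equal(mean(pat$sex == "male"), 38 / 52, tolerance = 0.02)
  expect_equal(mean(ctl$sex == "male"), 9 / 22, tolerance = 0.02)
})

test_that("noiseless planted cohort gives patient z-maps that are negative images of the template", {
  grid <- c(10, 10, 10)
  atl <- generate_atlas(grid, 25, seed = 20)
  tpl <- generate_template_maps(atl, 3, seed = 21)
  cfg <- synthetic_config(grid_shape = grid, n_regions = 25, n_templates = 3,
                          n_patients = 4, n_controls = 6,
                          planted_template_index = 2, effect_size_beta = 1,
                          noise_sd = 1e-9, confound_effects = c(age = 0),
                          seed = 22)
  coh <- generate_cohort(atl, tpl, cfg)
  rv <- extract_regional_means_cohort(coh$maps, atl)
  is_pat <- coh$subjects$group == "patient"
  # with (near) zero noise all controls are identical; compare regional values
  # directly: patient - control = -beta * template regional means
  diff <- rv[which(is_pat)[1], ] - rv[which(!is_pat)[1], ]
  expect_equal(unname(diff), unname(-tpl$regional[, 2]), tolerance = 1e-6)
  for (p in which(is_pat))
    expect_equal(spearman_rho(rv[p, ] - rv[which(!is_pat)[1], ],
                              tpl$regional[, 2]), -1)
})

test_that("null cohorts produce exchangeable groups", {
  # beta = 0, no confound effects: two-sample tests on regional means reject
  # at the nominal rate
  grid <- c(8, 8, 8)
  atl <- generate_atlas(grid, 12, seed = 30)
  tpl <- generate_template_maps(atl, 2, seed = 31)
  set.seed(32)
  ps <- replicate(100, {
    cfg <- synthetic_config(grid_shape = grid, n_regions = 12, n_templates = 2,
                            n_patients = 8, n_controls = 8,
                            planted_template_index = NA, effect_size_beta = 0,
                            confound_effects = c(age = 0),
                            seed = sample.int(1e6, 1))
    coh <- generate_cohort(atl, tpl, cfg)
    rv <- extract_regional_means_cohort(coh$maps, atl)
    is_pat <- coh$subjects$group == "patient"
    t.test(rowMeans(rv)[is_pat], rowMeans(rv)[!is_pat])$p.value
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("synthetic BOLD carries usable nuisance channels", {
  ts <- generate_bold(20, 64, 2, 0.5, seed = 40)
  expect_equal(dim(ts$motion6), c(64L, 6L))
  expect_length(ts$wm_signal, 64)
  expect_length(ts$csf_signal, 64)
  f24 <- build_friston24(ts$motion6)
  cleaned <- nuisance_regress_timeseries(ts, cbind(f24, ts$wm_signal, ts$csf_signal))
  expect_equal(dim(cleaned$series), dim(ts$series))
})

test_that("clinical score generator hits the target rank correlation at the extremes", {
  strengths <- rnorm(30)
  tb <- data.frame(id = 1:30)
  perfect <- generate_clinical(tb, strengths, 1, seed = 50)
  expect_equal(spearman_rho(strengths, perfect$clinical_score), 1)
  set.seed(51)
  null_r <- replicate(50, {
    t0 <- generate_clinical(tb, strengths, 0, seed = sample.int(1e6, 1))
    spearman_rho(strengths, t0$clinical_score)
  })
  expect_lt(abs(mean(null_r)), 0.08)
  expect_error(generate_clinical(tb, strengths[1:3], 0.5), "length")
})

test_that("donor generator determinism and rho = 0 boundary", {
  a <- generate_donors(30, c("g1", "g2"), inter_donor_rho = 0.5, n_donors = 3,
                       seed = 60)
  b <- generate_donors(30, c("g1", "g2"), inter_donor_rho = 0.5, n_donors = 3,
                       seed = 60)
  expect_identical(a$donors, b$donors)
  set.seed(61)
  ds0 <- replicate(40, {
    d <- generate_donors(25, "g", inter_donor_rho = 0, n_donors = 4,
                         seed = sample.int(1e6, 1))
    gene_differential_stability(d, "g")$ds
  })
  expect_lt(abs(mean(ds0)), 0.05)
})
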