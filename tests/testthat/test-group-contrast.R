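make_maps <- function(mat, gs) lapply(seq_len(nrow(mat)), function(i)
  scalar_map(array(mat[i, ], gs)))

test_that("identical groups give t = 0 everywhere; known shift gives the closed-form t", {
  gs <- c(4, 4, 4)
  base <- rnorm(prod(gs))
  maps <- make_maps(matrix(base, 10, prod(gs), byrow = TRUE), gs)
  tb <- data.frame(group = rep(c("patient", "control"), each = 5))
  tm <- fit_voxelwise_glm(maps, tb, contrast = "control-patient")
  expect_true(all(tm$t == 0))
  expect_equal(tm$df, 8)
  # closed form: delta / (sigma * sqrt(1/n1 + 1/n2)) on average
  set.seed(1)
  n1 <- 60; n2 <- 40; delta <- 0.8; sigma <- 1
  mat <- rbind(matrix(rnorm(n1 * prod(gs), 0, sigma), n1),
               matrix(rnorm(n2 * prod(gs), delta, sigma), n2))
  tb2 <- data.frame(group = rep(c("patient", "control"), c(n1, n2)))
  tm2 <- fit_voxelwise_glm(make_maps(mat, gs), tb2, contrast = "control-patient")
  expected <- delta / (sigma * sqrt(1 / n1 + 1 / n2))
  expect_equal(mean(tm2$t), expected, tolerance = 0.1)
})

test_that("voxel t values match per-voxel lm() with covariates", {
  set.seed(2)
  gs <- c(3, 3, 3)
  n <- 16
  tb <- data.frame(group = rep(c("patient", "control"), each = 8),
                   age = rnorm(n), site = sample(c("x", "y"), n, replace = TRUE))
  mat <- matrix(rnorm(n * prod(gs)), n)
  tm <- fit_voxelwise_glm(make_maps(mat, gs), tb, c("age", "site"),
                          "control-patient")
  for (vx in sample(prod(gs), 6)) {
    fit <- summary(lm(mat[, vx] ~ I(tb$group == "control") + age + site, data = tb))
    expect_equal(as.numeric(tm$t)[vx], fit$coefficients[2, "t value"],
                 tolerance = 1e-8)
  }
  expect_equal(tm$df, n - 4)
})

test_that("connected components respect the requested connectivity", {
  a <- array(FALSE, c(4, 4, 1))
  a[1, 1, 1] <- TRUE; a[2, 2, 1] <- TRUE  # edge-diagonal neighbors
  expect_length(neurocoloc:::connected_components(a, 6L), 2)
  expect_length(neurocoloc:::connected_components(a, 18L), 1)
  b <- array(FALSE, c(3, 3, 3))
  b[1, 1, 1] <- TRUE; b[2, 2, 2] <- TRUE  # corner-diagonal neighbors
  expect_length(neurocoloc:::connected_components(b, 18L), 2)
  expect_length(neurocoloc:::connected_components(b, 26L), 1)
})

test_that("cluster inference: p-value floor, connectivity leaves t untouched, subject order irrelevant", {
  set.seed(3)
  gs <- c(8, 8, 8)
  n <- 20
  mat <- matrix(rnorm(n * prod(gs)), n)
  # plant a strong cube in controls
  cube <- array(FALSE, gs); cube[3:6, 3:6, 3:6] <- TRUE
  is_ctl <- rep(c(FALSE, TRUE), each = 10)
  mat[is_ctl, as.logical(cube)] <- mat[is_ctl, as.logical(cube)] + 3
  tb <- data.frame(id = sprintf("s%02d", 1:n),
                   group = ifelse(is_ctl, "control", "patient"))
  ct <- permutation_cluster_inference(make_maps(mat, gs), tb, n_perm = 100,
                                      seed = 9, all_clusters = TRUE)
  top <- ct$clusters[1, ]
  expect_gte(top$size, 50)
  expect_equal(top$p, 1 / 101)
  # planted cube recovered (Jaccard > 0.5)
  cl_mask <- largest_cluster_mask(ct)
  jac <- sum(cl_mask & cube) / sum(cl_mask | cube)
  expect_gt(jac, 0.5)
  # connectivity changes clustering only, never the t map
  ct6 <- permutation_cluster_inference(make_maps(mat, gs), tb, n_perm = 100,
                                       seed = 9, connectivity = 6L,
                                       all_clusters = TRUE)
  expect_identical(ct6$tmap$t, ct$tmap$t)
  # permuting subject rows (with maps) leaves the whole result identical
  perm <- sample(n)
  ct_perm <- permutation_cluster_inference(make_maps(mat[perm, ], gs),
                                           tb[perm, , drop = FALSE],
                                           n_perm = 100, seed = 9,
                                           all_clusters = TRUE)
  expect_equal(ct_perm$tmap$t, ct$tmap$t, tolerance = 1e-12)
  expect_equal(ct_perm$clusters, ct$clusters)
  # cluster p bounded by the add-one convention
  expect_true(all(ct$clusters$p >= 1 / 101 & ct$clusters$p <= 1))
})

test_that("planted group differences are recovered across replicates", {
  gs <- c(8, 8, 8)
  cube <- array(FALSE, gs); cube[3:6, 3:6, 3:6] <- TRUE
  hits <- 0L
  for (rep in 1:5) {
    set.seed(100 + rep)
    n <- 24
    mat <- matrix(rnorm(n * prod(gs)), n)
    is_ctl <- rep(c(FALSE, TRUE), each = 12)
    mat[is_ctl, as.logical(cube)] <- mat[is_ctl, as.logical(cube)] + 2
    tb <- data.frame(group = ifelse(is_ctl, "control", "patient"))
    ct <- permutation_cluster_inference(make_maps(mat, gs), tb, n_perm = 100,
                                        seed = rep)
    if (nrow(ct$clusters)) {
      cl_mask <- largest_cluster_mask(ct)
      if (sum(cl_mask & cube) / sum(cl_mask | cube) > 0.5) hits <- hits + 1L
    }
  }
  expect_gte(hits, 4L)
})
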