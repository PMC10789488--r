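test_that("gray-matter masking keeps in-mask values bit-identical", {
  set.seed(1)
  v <- array(rnorm(4^3), dim = c(4, 4, 4))
  all_in <- apply_gm_mask(v, array(TRUE, dim = dim(v)))
  expect_identical(all_in$values, v)
  all_out <- apply_gm_mask(v, array(FALSE, dim = dim(v)))
  expect_true(all(is.na(all_out$values)))
  m <- array(runif(4^3) > 0.5, dim = dim(v))
  mixed <- apply_gm_mask(v, m)
  expect_identical(mixed$values[m], v[m])
  expect_true(all(is.na(mixed$values[!m])))
  expect_error(apply_gm_mask(v, array(TRUE, dim = c(2, 2, 2))), "shape")
})

test_that("image confound regression matches explicit normal equations", {
  set.seed(2)
  gs <- c(5, 5, 4)
  n <- 14
  tb <- data.frame(age = rnorm(n, 60, 8),
                   sex = sample(c("male", "female"), n, replace = TRUE),
                   site = sample(c("a", "b", "c"), n, replace = TRUE))
  maps <- lapply(1:n, function(i) scalar_map(array(rnorm(prod(gs)), gs)))
  out <- regress_confounds_images(maps, tb, c("age", "sex", "site"))
  # oracle: dummy-coded centered design, explicit solve, per voxel
  X <- cbind(1, scale(cbind(tb$age,
                            as.numeric(tb$sex == "male"),
                            as.numeric(tb$site == "b"),
                            as.numeric(tb$site == "c")), scale = FALSE))
  for (vx in sample(prod(gs), 10)) {
    y <- vapply(maps, function(m) m$values[vx], numeric(1))
    expect_equal(vapply(out, function(m) m$values[vx], numeric(1)),
                 ols_residuals_oracle(X, y) + mean(y), tolerance = 1e-10)
  }
})

test_that("confound regression preserves orthogonal signal, kills linear signal, and is idempotent", {
  set.seed(3)
  gs <- c(4, 4, 4)
  n <- 12
  age <- rnorm(n)
  # values orthogonal to age by construction: project age out voxel-wise
  raw <- matrix(rnorm(n * prod(gs)), n)
  Xa <- cbind(1, age - mean(age))
  ortho <- raw - Xa %*% solve(t(Xa) %*% Xa, t(Xa) %*% raw)
  ortho <- sweep(ortho, 2, colMeans(raw) - colMeans(ortho), "+")  # restore means
  maps <- lapply(1:n, function(i) scalar_map(array(ortho[i, ], gs)))
  tb <- data.frame(age = age)
  out <- regress_confounds_images(maps, tb, "age")
  for (i in 1:n) expect_equal(out[[i]]$values, maps[[i]]$values, tolerance = 1e-8)
  # exactly linear in age, zero noise -> flat at the voxel grand mean
  pat <- array(rnorm(prod(gs)), gs)
  maps2 <- lapply(1:n, function(i) scalar_map(5 + age[i] * pat))
  out2 <- regress_confounds_images(maps2, tb, "age")
  resid_var <- apply(vapply(out2, function(m) as.numeric(m$values),
                            numeric(prod(gs))), 1, var)
  expect_true(all(resid_var < 1e-20))
  # idempotence
  once <- regress_confounds_images(maps2, tb, "age")
  twice <- regress_confounds_images(once, tb, "age")
  for (i in 1:n)
    expect_equal(twice[[i]]$values, once[[i]]$values, tolerance = 1e-8)
})

test_that("rank-deficient confound designs fail loudly, naming columns", {
  tb <- data.frame(age = 1:6, age2 = 2 * (1:6),
                   group = rep(c("patient", "control"), 3))
  maps <- lapply(1:6, function(i) scalar_map(array(rnorm(8), c(2, 2, 2))))
  expect_error(regress_confounds_images(maps, tb, c("age", "age2")), "age2")
})

test_that("regional means equal an explicit voxel loop and respect missingness", {
  atl <- generate_atlas(c(8, 8, 8), 5, seed = 4)
  # constant map
  cmap <- scalar_map(array(3.5, dim = c(8, 8, 8)), mask = atl$labels > 0)
  expect_equal(unname(extract_regional_means(cmap, atl)), rep(3.5, 5))
  # random map vs loop
  set.seed(5)
  v <- array(rnorm(512), dim = c(8, 8, 8))
  m <- scalar_map(v, mask = atl$labels > 0)
  got <- extract_regional_means(m, atl)
  for (r in 1:5) {
    acc <- c()
    for (i in 1:8) for (j in 1:8) for (k in 1:8)
      if (atl$labels[i, j, k] == r) acc <- c(acc, v[i, j, k])
    expect_equal(unname(got[r]), mean(acc))
  }
  # region fully outside the mask is NA, not 0
  mask2 <- atl$labels > 0 & atl$labels != 2
  m2 <- scalar_map(v, mask = mask2)
  got2 <- extract_regional_means(m2, atl)
  expect_true(is.na(got2["2"]))
  expect_equal(got2[-2], got[-2])
})

test_that("regional extraction is equivariant under region relabeling", {
  atl <- generate_atlas(c(8, 8, 8), 6, seed = 6)
  set.seed(6)
  v <- array(rnorm(512), dim = c(8, 8, 8))
  m <- scalar_map(v, mask = atl$labels > 0)
  perm <- sample(6)
  lab2 <- atl$labels
  lab2[atl$labels > 0] <- perm[atl$labels[atl$labels > 0]]
  atl2 <- atlas(lab2)
  g1 <- extract_regional_means(m, atl)
  g2 <- extract_regional_means(m, atl2)
  expect_equal(unname(g2[perm]), unname(g1))
})

test_that("eigenvariate recovers rank-1 structure with the cluster-mean sign anchor", {
  set.seed(7)
  gs <- c(4, 4, 3)
  cl <- array(FALSE, gs); cl[1:2, 1:3, 1] <- TRUE
  u <- rnorm(9); v <- abs(rnorm(sum(cl))) + 0.5
  maps <- lapply(1:9, function(i) {
    a <- array(rnorm(prod(gs), sd = 1e-8), gs)
    a[cl] <- u[i] * v
    scalar_map(a)
  })
  sc <- extract_eigenvariate(maps, cl)
  expect_equal(abs(cor(sc, u)), 1, tolerance = 1e-6)
  expect_equal(sd(sc), 1, tolerance = 1e-8)
  # sign convention on random data
  for (s in 1:10) {
    maps2 <- lapply(1:8, function(i) scalar_map(array(rnorm(prod(gs)), gs)))
    sc2 <- extract_eigenvariate(maps2, cl)
    cm <- vapply(maps2, function(m) mean(m$values[cl]), numeric(1))
    expect_gte(cor(sc2, cm), 0)
  }
  expect_error(extract_eigenvariate(maps, array(FALSE, gs)), "empty")
})
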