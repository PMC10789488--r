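# Brute-force reference implementations, kept deliberately independent of the
# package code paths they check.

# average ranks via order() and run-length averaging (no rank())
manual_rank <- function(x) {
  n <- length(x)
  o <- order(x)
  r <- numeric(n)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && x[o[j + 1]] == x[o[i]]) j <- j + 1
    r[o[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

pearson_oracle <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

spearman_oracle <- function(x, y) pearson_oracle(manual_rank(x), manual_rank(y))

# partial rank correlation through the recursive partial-correlation formula
partial_spearman_recursive_oracle <- function(x, y, z) {
  rxy <- spearman_oracle(x, y)
  rxz <- spearman_oracle(x, z)
  ryz <- spearman_oracle(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# residual-of-ranks route (the construction the package claims to implement)
partial_spearman_residual_oracle <- function(x, y, z) {
  rx <- manual_rank(x); ry <- manual_rank(y); rz <- manual_rank(z)
  X <- cbind(1, rz)
  bx <- solve(t(X) %*% X, t(X) %*% rx)
  by <- solve(t(X) %*% X, t(X) %*% ry)
  pearson_oracle(rx - X %*% bx, ry - X %*% by)
}

# exhaustive Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  q[o[m]] <- p[o[m]]
  for (i in seq(m - 1, 1)) {
    if (i < 1) break
    q[o[i]] <- min(p[o[i]] * m / i, q[o[i + 1]])
  }
  pmin(q, 1)
}

# AUC by explicit pair enumeration, ties half
auc_pairs_oracle <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

# OLS residuals by explicit normal equations
ols_residuals_oracle <- function(X, y) {
  as.numeric(y - X %*% solve(t(X) %*% X, t(X) %*% y))
}

# first principal scores by power iteration on the centered matrix
eigenvariate_oracle <- function(M) {
  Mc <- sweep(M, 2, colMeans(M))
  A <- Mc %*% t(Mc)
  v <- rep(1, nrow(A)) + seq_len(nrow(A)) * 1e-3
  for (i in 1:1000) {
    v2 <- A %*% v
    nv <- sqrt(sum(v2^2))
    if (nv == 0) break
    v2 <- v2 / nv
    if (sum((v2 - v)^2) < 1e-24) { v <- v2; break }
    v <- v2
  }
  scores <- as.numeric(v)
  if (sd(scores) > 0) scores <- scores / sd(scores)
  cm <- rowMeans(M)
  if (sd(cm) > 0 && cor(scores, cm) < 0) scores <- -scores
  scores
}

# hand Kruskal-Wallis H with tie correction
kruskal_oracle <- function(values, groups) {
  n <- length(values)
  r <- manual_rank(values)
  groups <- as.character(groups)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# small random cohort on a tiny grid, for integration-style tests
tiny_cohort <- function(n_pat = 10, n_ctl = 6, n_regions = 30,
                        grid = c(10, 10, 10), n_templates = 4,
                        beta = 0, planted = 1, seed = 1) {
  atl <- generate_atlas(grid, n_regions, seed = seed)
  tpl <- generate_template_maps(atl, n_templates, seed = seed + 1)
  cfg <- synthetic_config(grid_shape = grid, n_regions = n_regions,
                          n_templates = n_templates, n_patients = n_pat,
                          n_controls = n_ctl,
                          planted_template_index = planted,
                          effect_size_beta = beta, noise_sd = 1,
                          seed = seed + 2)
  coh <- generate_cohort(atl, tpl, cfg)
  list(atlas = atl, templates = tpl, config = cfg, cohort = coh)
}
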