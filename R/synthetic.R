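#' Synthetic study configuration
#'
#' Bundles every knob of the synthetic cohort generator. Defaults emulate the
#' study conditions: 52 patients and 22 controls, demographics matching the
#' cohort table (patient age ~ N(61.5, 10.0^2), control age ~ N(63.6,
#' 11.9^2), sex frequencies 38/14 and 9/13), 11 neurotransmitter-like
#' template maps, and a planted negative co-localization effect on one
#' template.
#'
#' @param grid_shape Voxel grid, 3 positive integers.
#' @param n_regions Number of atlas regions (must not exceed in-mask voxels).
#' @param n_templates Number of template density maps.
#' @param n_patients,n_controls Group sizes.
#' @param planted_template_index 1-based index of the template carrying the
#'   planted effect, or `NA` for a null cohort.
#' @param effect_size_beta Map units per unit template; the sign of the
#'   patient change is negative (patients lose signal where density is high).
#' @param noise_sd Voxel noise SD.
#' @param confound_effects Named numeric coefficients for covariate effects
#'   on the maps (names among `age`, `sex`, `site`, `tiv`); each acts through
#'   a fixed smooth spatial pattern.
#' @param n_sites Number of acquisition sites.
#' @param inter_donor_rho Target pairwise population Spearman correlation
#'   between expression donors.
#' @param n_donors Number of expression donors.
#' @param seed Integer seed.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(grid_shape = c(16L, 16L, 16L), n_regions = 60L,
                             n_templates = 11L, n_patients = 52L,
                             n_controls = 22L, planted_template_index = 1L,
                             effect_size_beta = 0, noise_sd = 1,
                             confound_effects = c(age = 0.01, sex = 0.2, site = 0.15),
                             n_sites = 3L, inter_donor_rho = 0.5,
                             n_donors = 6L, seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 2),
            n_regions >= 1L, n_templates >= 1L,
            n_patients >= 1L, n_controls >= 2L,
            noise_sd > 0, n_sites >= 1L, n_donors >= 1L,
            inter_donor_rho >= 0, inter_donor_rho < 1)
  if (!is.na(planted_template_index))
    stopifnot(planted_template_index >= 1L, planted_template_index <= n_templates)
  structure(list(grid_shape = as.integer(grid_shape), n_regions = as.integer(n_regions),
                 n_templates = as.integer(n_templates),
                 n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
                 planted_template_index = planted_template_index,
                 effect_size_beta = effect_size_beta, noise_sd = noise_sd,
                 confound_effects = confound_effects, n_sites = as.integer(n_sites),
                 inter_donor_rho = inter_donor_rho, n_donors = as.integer(n_donors),
                 seed = as.integer(seed)), class = "synthetic_config")
}

# Ellipsoidal "brain" mask centered on the grid: connected, covers a bit
# under half of the bounding box, like a GM mask on a small phantom grid.
ellipsoid_mask <- function(grid_shape) {
  g <- expand.grid(x = seq_len(grid_shape[1]), y = seq_len(grid_shape[2]),
                   z = seq_len(grid_shape[3]))
  c0 <- (grid_shape + 1) / 2
  r <- pmax((grid_shape - 1) / 2, 0.5)
  d <- ((g$x - c0[1]) / r[1])^2 + ((g$y - c0[2]) / r[2])^2 + ((g$z - c0[3]) / r[3])^2
  array(d <= 1, dim = grid_shape)
}

# Separable 3D Gaussian smoothing (sigma in voxels; 0 = no-op). Dense
# per-axis kernel matrices are fine at phantom grid sizes.
gaussian_smooth_3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  dims <- dim(arr)
  kmat <- function(d) {
    idx <- seq_len(d)
    K <- exp(-outer(idx, idx, function(a, b) (a - b)^2) / (2 * sigma^2))
    sweep(K, 1, rowSums(K), "/")
  }
  x <- arr
  x <- array(kmat(dims[1]) %*% matrix(x, dims[1]), dims)
  x <- aperm(array(kmat(dims[2]) %*% matrix(aperm(x, c(2, 1, 3)), dims[2]),
                   dims[c(2, 1, 3)]), c(2, 1, 3))
  x <- aperm(array(kmat(dims[3]) %*% matrix(aperm(x, c(3, 1, 2)), dims[3]),
                   dims[c(3, 1, 2)]), c(2, 3, 1))
  x
}

smooth_noise_map <- function(grid_shape, smoothness) {
  gaussian_smooth_3d(array(stats::rnorm(prod(grid_shape)), dim = grid_shape),
                     smoothness)
}

#' Generate a synthetic gray-matter atlas
#'
#' Partitions a connected ellipsoidal GM mask into `n_regions` contiguous
#' labels by k-means on voxel coordinates. Labels 1..n_regions exactly
#' partition the mask; 0 is background. Deterministic for a given seed.
#'
#' @param grid_shape 3 positive integers.
#' @param n_regions Number of regions (<= in-mask voxel count).
#' @param seed Integer seed.
#' @return An [atlas()].
#' @export
generate_atlas <- function(grid_shape, n_regions, seed = 1L) {
  mask <- ellipsoid_mask(grid_shape)
  n_vox <- sum(mask)
  if (n_regions > n_vox)
    stop("generate_atlas: n_regions (", n_regions, ") exceeds in-mask voxels (",
         n_vox, ")")
  set.seed(seed)
  coords <- arrayInd(which(mask), grid_shape)
  lab_in <- if (n_regions == 1L) rep(1L, n_vox) else
    stats::kmeans(coords + stats::runif(length(coords), -1e-3, 1e-3),
                  centers = n_regions, iter.max = 100L, nstart = 1L)$cluster
  # relabel contiguously in order of first appearance for determinism
  lab_in <- as.integer(factor(lab_in, levels = unique(lab_in)))
  labels <- array(0L, dim = grid_shape)
  labels[mask] <- lab_in
  atlas(labels)
}

#' Generate synthetic neurotransmitter template maps
#'
#' Gaussian-smoothed white noise, rectified to nonnegative (shifted by the
#' in-mask minimum), masked to the atlas. Templates are regenerated (bounded
#' retries) until all pairwise |Spearman| correlations of their regional
#' means are below `cap`, so planted effects stay attributable to one map.
#'
#' @param atlas An [atlas()].
#' @param n_templates Number of maps.
#' @param smoothness Gaussian sigma in voxels (0 = voxelwise independent
#'   noise).
#' @param seed Integer seed.
#' @param cap Maximum allowed pairwise |Spearman| of regional means.
#' @param max_retries Resampling attempts per offending template.
#' @return List with `maps` (list of `scalar_map`), `regional` (regions x
#'   templates matrix of regional means).
#' @export
generate_template_maps <- function(atlas, n_templates, smoothness = 1.5,
                                   seed = 1L, cap = 0.3, max_retries = 200L) {
  mask <- atlas$labels > 0L
  set.seed(seed)
  make_one <- function() {
    m <- smooth_noise_map(dim(atlas$labels), smoothness)
    m <- m - min(m[mask])
    scalar_map(m, mask = mask)
  }
  maps <- lapply(seq_len(n_templates), function(i) make_one())
  reg <- vapply(maps, extract_regional_means, numeric(atlas$n_regions), atlas = atlas)
  tries <- 0L
  repeat {
    if (n_templates < 2L) break
    cm <- abs(stats::cor(reg, method = "spearman"))
    diag(cm) <- 0
    if (max(cm) <= cap) break
    if (tries >= max_retries)
      stop("generate_template_maps: could not satisfy pairwise |rho| <= ", cap,
           " after ", max_retries, " retries")
    worst <- which.max(apply(cm, 2, max))
    maps[[worst]] <- make_one()
    reg[, worst] <- extract_regional_means(maps[[worst]], atlas)
    tries <- tries + 1L
  }
  colnames(reg) <- sprintf("template_%02d", seq_len(n_templates))
  list(maps = maps, regional = reg)
}

#' Generate a synthetic subject cohort with a planted co-localization effect
#'
#' Control map_i = baseline + covariate effects + noise; patient map_i =
#' baseline - effect_size_beta x planted template + covariate effects +
#' noise. Demographics (age, sex, site, TIV) are drawn from the configured
#' distributions; each covariate in `confound_effects` acts through a fixed
#' smooth spatial pattern. Ground truth (beta, planted index) is returned in
#' a sidecar list.
#'
#' @param atlas An [atlas()].
#' @param templates Output of [generate_template_maps()].
#' @param config A [synthetic_config()].
#' @return List with `subjects` (data frame: id, group, age, sex, site, tiv),
#'   `maps` (list of `scalar_map`, subject order), and `ground_truth`
#'   (beta, planted_template_index, baseline map, seed).
#' @export
generate_cohort <- function(atlas, templates, config) {
  stopifnot(inherits(config, "synthetic_config"))
  mask <- atlas$labels > 0L
  gs <- dim(atlas$labels)
  set.seed(config$seed)
  n_p <- config$n_patients; n_c <- config$n_controls; n <- n_p + n_c
  subjects <- data.frame(
    id = sprintf("sub-%03d", seq_len(n)),
    group = rep(c("patient", "control"), c(n_p, n_c)),
    age = c(stats::rnorm(n_p, 61.5, 10.0), stats::rnorm(n_c, 63.6, 11.9)),
    sex = c(sample(rep(c("male", "female"),
                       c(round(n_p * 38 / 52), n_p - round(n_p * 38 / 52)))),
            sample(rep(c("male", "female"),
                       c(round(n_c * 9 / 22), n_c - round(n_c * 9 / 22))))),
    site = sprintf("site_%d", 1L + (seq_len(n) - 1L) %% config$n_sites),
    tiv = stats::rnorm(n, 1450, 130),
    stringsAsFactors = FALSE)
  subjects$site <- sample(subjects$site)
  baseline <- gaussian_smooth_3d(array(stats::rnorm(prod(gs)), gs), 1.5)
  patterns <- lapply(config$confound_effects, function(b)
    gaussian_smooth_3d(array(stats::rnorm(prod(gs)), gs), 1.5))
  planted <- if (!is.na(config$planted_template_index))
    templates$maps[[config$planted_template_index]]$values else NULL
  covar_num <- list(
    age = subjects$age - mean(subjects$age),
    sex = as.numeric(subjects$sex == "male") - mean(subjects$sex == "male"),
    site = as.numeric(factor(subjects$site)) - mean(as.numeric(factor(subjects$site))),
    tiv = (subjects$tiv - mean(subjects$tiv)) / 100)
  maps <- vector("list", n)
  for (i in seq_len(n)) {
    v <- baseline
    for (cv in names(config$confound_effects))
      v <- v + config$confound_effects[[cv]] * covar_num[[cv]][i] * patterns[[cv]]
    if (subjects$group[i] == "patient" && !is.null(planted) &&
        config$effect_size_beta != 0) {
      pl <- planted; pl[is.na(pl)] <- 0
      v <- v - config$effect_size_beta * pl
    }
    v <- v + array(stats::rnorm(prod(gs), 0, config$noise_sd), gs)
    maps[[i]] <- scalar_map(v, mask = mask)
  }
  list(subjects = subjects, maps = maps,
       ground_truth = list(beta = config$effect_size_beta,
                           planted_template_index = config$planted_template_index,
                           baseline = baseline, seed = config$seed))
}

#' Generate synthetic BOLD time series with a controlled in-band power share
#'
#' Spectral synthesis: per voxel, independent Gaussian Fourier coefficients
#' whose expected power is split between the analysis band (0.01-0.08 Hz by
#' default) and the rest of the positive spectrum so the expected in-band
#' power fraction equals `band_power_fraction`. Also returns synthetic
#' six-parameter motion (random walk) and mean WM/CSF signals for
#' nuisance-regression tests.
#'
#' @param n_voxels,n_volumes Dimensions of the series (>= 16 volumes).
#' @param tr_seconds Repetition time (study value 2.0).
#' @param band_power_fraction Expected in-band power share, in \[0, 1\].
#' @param seed Integer seed.
#' @param low_hz,high_hz Analysis band.
#' @return A [timeseries_set()].
#' @export
generate_bold <- function(n_voxels, n_volumes, tr_seconds = 2,
                          band_power_fraction = 0.5, seed = 1L,
                          low_hz = 0.01, high_hz = 0.08) {
  stopifnot(n_volumes >= 16L, band_power_fraction >= 0, band_power_fraction <= 1)
  nyquist <- 1 / (2 * tr_seconds)
  if (high_hz > nyquist + 1e-12)
    stop("generate_bold: band upper edge ", high_hz,
         " Hz exceeds Nyquist ", signif(nyquist, 4), " Hz for tr = ", tr_seconds)
  set.seed(seed)
  n_pos <- floor(n_volumes / 2)
  freqs <- seq_len(n_pos) / (n_volumes * tr_seconds)
  in_band <- freqs >= low_hz - 1e-12 & freqs <= high_hz + 1e-12
  n_in <- sum(in_band); n_out <- n_pos - n_in
  if (n_in == 0L) stop("generate_bold: no frequency bins inside the band")
  v <- ifelse(in_band, band_power_fraction / n_in,
              if (n_out > 0) (1 - band_power_fraction) / n_out else 0)
  coef_re <- matrix(stats::rnorm(n_pos * n_voxels), n_pos) * sqrt(v / 2)
  coef_im <- matrix(stats::rnorm(n_pos * n_voxels), n_pos) * sqrt(v / 2)
  even <- n_volumes %% 2L == 0L
  if (even) { # Nyquist bin must be real
    coef_re[n_pos, ] <- coef_re[n_pos, ] * sqrt(2)
    coef_im[n_pos, ] <- 0
  }
  spec <- matrix(0 + 0i, n_volumes, n_voxels)
  spec[1 + seq_len(n_pos), ] <- complex(real = coef_re, imaginary = coef_im)
  mirror <- if (even) seq_len(n_pos - 1L) else seq_len(n_pos)
  spec[n_volumes + 1L - mirror, ] <- Conj(spec[1L + mirror, ])
  series <- t(Re(stats::mvfft(spec, inverse = TRUE))) * sqrt(n_volumes) / sqrt(2)
  motion6 <- apply(matrix(stats::rnorm(n_volumes * 6, 0, 0.02), n_volumes), 2, cumsum)
  timeseries_set(series, tr_seconds, motion6 = motion6,
                 wm_signal = as.numeric(stats::filter(stats::rnorm(n_volumes), 0.5,
                                                      method = "recursive")),
                 csf_signal = as.numeric(stats::filter(stats::rnorm(n_volumes), 0.5,
                                                       method = "recursive")))
}

#' Generate synthetic expression donors
#'
#' Per gene, donors share a common latent regional pattern; each donor is
#' `sqrt(a) * latent + sqrt(1-a) * noise` with `a` chosen (via the
#' bivariate-normal rank-correlation identity `r_pearson = 2*sin(pi*rho/6)`) so
#' the pairwise population Spearman correlation equals `inter_donor_rho`.
#' Optionally the latent is the (standardized) regional pattern of a template
#' map, coupling expression to that neurotransmitter's distribution.
#'
#' @param regions Number of regions, or an [atlas()] (its region count).
#' @param gene_names Character vector of genes to simulate.
#' @param coupling_templates Optional named list mapping a gene name to a
#'   regional vector used as that gene's latent pattern.
#' @param inter_donor_rho Target pairwise Spearman in \[0, 1).
#' @param n_donors Number of donors (study value 6).
#' @param seed Integer seed.
#' @return A [donor_expression_set()].
#' @export
generate_donors <- function(regions, gene_names, coupling_templates = NULL,
                            inter_donor_rho = 0.5, n_donors = 6L, seed = 1L) {
  stopifnot(inter_donor_rho >= 0, inter_donor_rho < 1, n_donors >= 1L)
  n_reg <- if (inherits(regions, "atlas")) regions$n_regions else as.integer(regions)
  set.seed(seed)
  a <- 2 * sin(pi * inter_donor_rho / 6)
  donors <- lapply(seq_len(n_donors), function(d)
    matrix(NA_real_, n_reg, length(gene_names),
           dimnames = list(NULL, gene_names)))
  for (g in gene_names) {
    cp <- coupling_templates[[g]]
    latent <- if (!is.null(cp)) as.numeric(scale(cp)) else stats::rnorm(n_reg)
    for (d in seq_len(n_donors))
      donors[[d]][, g] <- sqrt(a) * latent + sqrt(1 - a) * stats::rnorm(n_reg)
  }
  names(donors) <- sprintf("donor_%d", seq_len(n_donors))
  donor_expression_set(donors)
}

#' Append a synthetic clinical score with a target rank correlation
#'
#' Adds a score column whose population Spearman correlation with the given
#' per-subject co-localization strengths equals `target_rho`, via a Gaussian
#' copula on the normal scores of the strengths (Pearson coupling
#' `2 sin(pi rho / 6)`).
#'
#' @param subject_table Data frame (one row per subject carrying a strength).
#' @param coloc_strengths Numeric vector, one value per row of
#'   `subject_table`.
#' @param target_rho Target Spearman in \[-1, 1\].
#' @param seed Integer seed.
#' @param score_name Name of the appended column.
#' @return `subject_table` with the new score column.
#' @export
generate_clinical <- function(subject_table, coloc_strengths, target_rho,
                              seed = 1L, score_name = "clinical_score") {
  if (length(coloc_strengths) != nrow(subject_table))
    stop("generate_clinical: coloc_strengths length != number of subjects")
  stopifnot(abs(target_rho) <= 1)
  set.seed(seed)
  n <- length(coloc_strengths)
  latent <- stats::qnorm((rank(coloc_strengths) - 0.5) / n)
  r <- 2 * sin(pi * target_rho / 6)
  score <- if (abs(r) >= 1) sign(r) * latent
           else r * latent + sqrt(1 - r^2) * stats::rnorm(n)
  subject_table[[score_name]] <- score
  subject_table
}

#' Calibrate the planted effect size to a target mean co-localization
#'
#' Monte-Carlo bisection: for a candidate beta, generate replicate cohorts,
#' run the confound regression + regional extraction + z-scoring chain, and
#' measure the mean patient Spearman correlation with the planted template;
#' bisect until the mean correlation hits `target_rho`. The calibration log
#' (beta, mean rho per evaluation) is returned alongside.
#'
#' @param atlas,templates,config As for [generate_cohort()]; the config's
#'   `planted_template_index` must be set.
#' @param target_rho Target mean patient Spearman (study-scale value -0.2).
#' @param n_rep Replicate cohorts per beta evaluation.
#' @param beta_hi Upper bracket for the search.
#' @param tol Stop when the bracketed mean rho is within this of the target.
#' @param seed Integer seed (independent of the config seed).
#' @return List with `beta`, `achieved_rho`, and `log` (data frame).
#' @export
calibrate_effect_size <- function(atlas, templates, config, target_rho = -0.2,
                                  n_rep = 20L, beta_hi = NULL, tol = 0.01,
                                  seed = 99L) {
  stopifnot(!is.na(config$planted_template_index))
  tpl_rv <- templates$regional[, config$planted_template_index]
  covs <- intersect(names(config$confound_effects), c("age", "sex", "site", "tiv"))
  mean_rho_for <- function(beta, eval_seed) {
    cfg <- config
    cfg$effect_size_beta <- beta
    rhos <- vapply(seq_len(n_rep), function(r) {
      cfg$seed <- (eval_seed + 7L * r) %% .Machine$integer.max
      coh <- generate_cohort(atlas, templates, cfg)
      maps <- regress_confounds_images(coh$maps, coh$subjects, covs)
      rv <- extract_regional_means_cohort(maps, atlas)
      is_pat <- coh$subjects$group == "patient"
      zm <- t(apply(rv[is_pat, , drop = FALSE], 1, zscore_vs_controls,
                    control_rvs = rv[!is_pat, , drop = FALSE]))
      mean(apply(zm, 1, spearman_rho, y = tpl_rv), na.rm = TRUE)
    }, numeric(1))
    mean(rhos)
  }
  if (is.null(beta_hi)) beta_hi <- 4 * config$noise_sd
  log <- data.frame(beta = numeric(), mean_rho = numeric())
  note <- function(b, r) log[nrow(log) + 1L, ] <<- c(b, r)
  lo <- 0; hi <- beta_hi
  r_hi <- mean_rho_for(hi, seed); note(hi, r_hi)
  tries <- 0L
  while (r_hi > target_rho && tries < 6L) {
    hi <- hi * 2; r_hi <- mean_rho_for(hi, seed + tries + 1L); note(hi, r_hi)
    tries <- tries + 1L
  }
  if (r_hi > target_rho)
    stop("calibrate_effect_size: target not reachable with beta <= ", hi)
  mid <- hi; r_mid <- r_hi
  for (it in seq_len(20L)) {
    mid <- (lo + hi) / 2
    r_mid <- mean_rho_for(mid, seed + 100L + it)
    note(mid, r_mid)
    if (abs(r_mid - target_rho) < tol) break
    if (r_mid > target_rho) lo <- mid else hi <- mid
  }
  list(beta = mid, achieved_rho = r_mid, log = log)
}
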