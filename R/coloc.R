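#' Regional z-map of a patient relative to controls
#'
#' Per region, (patient - mean(controls)) / sd(controls), with the sample
#' (n-1) SD. Regions with zero control SD, or missing in the patient or any
#' needed control moment, are returned `NA`.
#'
#' @param patient_rv Named regional vector (one value per region, `NA` =
#'   missing), as from [extract_regional_means()].
#' @param control_rvs Matrix of control regional vectors (controls x regions),
#'   >= 2 rows.
#' @return Regional z vector, same length/names as `patient_rv`.
#' @export
zscore_vs_controls <- function(patient_rv, control_rvs) {
  control_rvs <- as.matrix(control_rvs)
  if (nrow(control_rvs) < 2L) stop("zscore_vs_controls: need >= 2 controls")
  stopifnot(ncol(control_rvs) == length(patient_rv))
  mu <- colMeans(control_rvs)
  sdv <- apply(control_rvs, 2, stats::sd)
  z <- (patient_rv - mu) / sdv
  z[!is.finite(z)] <- NA_real_
  z
}

#' Leave-one-out control z-maps
#'
#' Each control z-scored against the mean/SD of the remaining controls,
#' making control co-localization profiles comparable to patient profiles.
#'
#' @param control_rvs Controls x regions matrix (>= 3 rows).
#' @return Matrix of the same shape holding the leave-one-out z-maps.
#' @export
loo_control_zscores <- function(control_rvs) {
  control_rvs <- as.matrix(control_rvs)
  n <- nrow(control_rvs)
  if (n < 3L) stop("loo_control_zscores: need >= 3 controls")
  out <- control_rvs
  for (i in seq_len(n))
    out[i, ] <- zscore_vs_controls(control_rvs[i, ], control_rvs[-i, , drop = FALSE])
  out
}

#' Fisher-z Spearman co-localization coefficient
#'
#' Spearman correlation between a subject's regional z-map and a template's
#' regional means over jointly non-missing regions, optionally as a partial
#' Spearman controlling for the regional gray-matter probability vector
#' (partial Pearson on average-ranked data). Returned on the Fisher-z scale
#' with the input correlation clipped to |rho| <= 1 - 1e-6.
#'
#' @param zmap Regional z vector.
#' @param template_rv Template regional means, same regions.
#' @param gm_rv Regional GM probabilities (required when `adjust_gm`).
#' @param adjust_gm Partial out the GM vector (default FALSE).
#' @return Scalar Fisher-z coefficient.
#' @export
coloc_profile <- function(zmap, template_rv, gm_rv = NULL, adjust_gm = FALSE) {
  stopifnot(length(zmap) == length(template_rv))
  ok <- is.finite(zmap) & is.finite(template_rv)
  if (adjust_gm) {
    stopifnot(!is.null(gm_rv), length(gm_rv) == length(zmap))
    ok <- ok & is.finite(gm_rv)
  }
  if (sum(ok) < 4L) stop("coloc_profile: fewer than 4 jointly non-missing regions")
  r <- if (adjust_gm) partial_spearman(zmap[ok], template_rv[ok], gm_rv[ok])
       else spearman_rho(zmap[ok], template_rv[ok])
  if (is.na(r)) return(NA_real_)
  fisher_z(r)
}

# Per-patient x template Fisher-z profile matrix (R reference path).
coloc_profiles_r <- function(patient_zmaps, templates, gm_rv = NULL, adjust_gm = FALSE) {
  out <- matrix(NA_real_, nrow(patient_zmaps), ncol(templates),
                dimnames = list(rownames(patient_zmaps), colnames(templates)))
  for (i in seq_len(nrow(patient_zmaps)))
    for (k in seq_len(ncol(templates)))
      out[i, k] <- coloc_profile(patient_zmaps[i, ], templates[, k], gm_rv, adjust_gm)
  out
}

#' Per-subject co-localization profiles
#'
#' Fisher-z Spearman coefficient of each subject's regional z-map with each
#' template. Patients are z-scored against all controls; with
#' `loo = TRUE` the subjects are controls and each is z-scored against the
#' remaining ones.
#'
#' @param subject_rvs Subjects x regions matrix of regional means.
#' @param control_rvs Controls x regions matrix.
#' @param templates Regions x templates matrix of template regional means.
#' @param gm_rv,adjust_gm See [coloc_profile()].
#' @param loo Leave-one-out mode for control profiles.
#' @return Subjects x templates matrix of Fisher-z coefficients.
#' @export
coloc_profiles <- function(subject_rvs, control_rvs, templates,
                           gm_rv = NULL, adjust_gm = FALSE, loo = FALSE) {
  subject_rvs <- as.matrix(subject_rvs); templates <- as.matrix(templates)
  zm <- if (loo) loo_control_zscores(subject_rvs)
        else t(apply(subject_rvs, 1, zscore_vs_controls, control_rvs = control_rvs))
  gm <- if (adjust_gm) gm_rv else NULL
  if (!anyNA(zm) && !anyNA(templates) && (!adjust_gm || !anyNA(gm))) {
    # fast path: complete data
    if (loo) {
      out <- coloc_profiles_r(zm, templates, gm, adjust_gm)
    } else {
      mu <- colMeans(control_rvs)
      sdv <- apply(control_rvs, 2, stats::sd)
      out <- .coloc_profiles_engine(subject_rvs, mu, sdv, templates,
                                    if (adjust_gm) gm else numeric(0))
      dimnames(out) <- list(rownames(subject_rvs), colnames(templates))
    }
    return(out)
  }
  coloc_profiles_r(zm, templates, gm, adjust_gm)
}

#' Permutation group test of co-localization
#'
#' Observed statistic per template: mean over patients of the Fisher-z
#' Spearman coefficients between patient z-maps (relative to controls) and
#' the template. The null is built by randomly reassigning subjects to
#' patient/control roles (group sizes preserved) and recomputing z-maps and
#' profiles for every permutation. Two-sided exact p with the add-one
#' convention; Benjamini-Hochberg FDR across templates; mean r is the
#' inverse Fisher transform of the mean Fisher z.
#'
#' @param patient_rvs,control_rvs Regional-mean matrices (subjects x regions).
#' @param templates Regions x templates matrix.
#' @param gm_rv,adjust_gm See [coloc_profile()].
#' @param n_perm Number of permutations (>= 100; study default 10000).
#' @param seed Integer seed for the permutation stream.
#' @return List of class `coloc_test`: data frame `table` (template, mean_z,
#'   mean_r, p, q), matrix `profiles` (patients x templates, observed
#'   Fisher-z), `null_means`, `n_perm`, `seed`.
#' @export
coloc_group_test <- function(patient_rvs, control_rvs, templates,
                             gm_rv = NULL, adjust_gm = FALSE,
                             n_perm = 10000L, seed = 1L) {
  patient_rvs <- as.matrix(patient_rvs); control_rvs <- as.matrix(control_rvs)
  templates <- as.matrix(templates)
  stopifnot(nrow(patient_rvs) >= 1L, nrow(control_rvs) >= 2L, n_perm >= 100L,
            ncol(patient_rvs) == nrow(templates),
            ncol(control_rvs) == nrow(templates))
  X <- rbind(patient_rvs, control_rvs)
  is_pat <- rep(c(TRUE, FALSE), c(nrow(patient_rvs), nrow(control_rvs)))
  gm <- if (adjust_gm) {
    stopifnot(!is.null(gm_rv), length(gm_rv) == nrow(templates))
    as.numeric(gm_rv)
  } else numeric(0)
  complete <- !anyNA(X) && !anyNA(templates) && !anyNA(gm)
  set.seed(seed)
  if (complete) {
    eng <- .coloc_perm_engine(X, is_pat, templates, gm, as.integer(n_perm))
    observed <- as.numeric(eng$observed)
    null_means <- eng$null
  } else {
    res <- coloc_perm_r(X, is_pat, templates, gm_rv, adjust_gm, n_perm)
    observed <- res$observed
    null_means <- res$null
  }
  if (anyNA(observed)) stop("coloc_group_test: degenerate region overlap")
  p <- vapply(seq_len(ncol(templates)), function(k)
    exact_perm_pvalue(observed[k], null_means[, k], "two.sided"), numeric(1))
  tpl_names <- colnames(templates)
  if (is.null(tpl_names)) tpl_names <- sprintf("template_%02d", seq_len(ncol(templates)))
  tab <- data.frame(template = tpl_names, mean_z = observed,
                    mean_r = fisher_z_inv(observed), p = p, q = bh_fdr(p),
                    stringsAsFactors = FALSE)
  profiles <- coloc_profiles(patient_rvs, control_rvs, templates,
                             gm_rv = gm_rv, adjust_gm = adjust_gm)
  colnames(profiles) <- tpl_names
  structure(list(table = tab, profiles = profiles, null_means = null_means,
                 n_perm = n_perm, seed = seed),
            class = "coloc_test")
}

# Pure-R permutation path (handles missing data; also the equivalence oracle
# for the compiled engine in the test suite).
coloc_perm_r <- function(X, is_pat, templates, gm_rv, adjust_gm, n_perm) {
  n_pat <- sum(is_pat)
  stat_for <- function(assign_pat) {
    pats <- X[assign_pat, , drop = FALSE]
    ctls <- X[!assign_pat, , drop = FALSE]
    zm <- t(apply(pats, 1, zscore_vs_controls, control_rvs = ctls))
    prof <- coloc_profiles_r(zm, templates, gm_rv, adjust_gm)
    colMeans(prof, na.rm = TRUE)
  }
  observed <- stat_for(is_pat)
  null <- matrix(NA_real_, n_perm, ncol(templates))
  n <- nrow(X)
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    assign_pat <- rep(FALSE, n)
    assign_pat[idx[seq_len(n_pat)]] <- TRUE
    null[b, ] <- stat_for(assign_pat)
  }
  list(observed = observed, null = null)
}

#' ROC discrimination of patients from controls by co-localization strength
#'
#' Per template, the AUC for discriminating patient Fisher-z coefficients
#' from control (leave-one-out) coefficients. The orientation is chosen so
#' the reported AUC is >= 0.5, with a flag recording the direction.
#'
#' @param patient_profiles Patients x templates Fisher-z matrix.
#' @param control_loo_profiles Controls x templates Fisher-z matrix (from
#'   leave-one-out control z-maps).
#' @return Data frame per template: `auc` (raw, patients-high), `auc_oriented`
#'   (>= 0.5), `orientation` (+1 patients score higher, -1 lower), plus
#'   a list-column `curve` of ROC points in the oriented direction.
#' @export
coloc_roc <- function(patient_profiles, control_loo_profiles) {
  patient_profiles <- as.matrix(patient_profiles)
  control_loo_profiles <- as.matrix(control_loo_profiles)
  if (!nrow(patient_profiles) || !nrow(control_loo_profiles))
    stop("coloc_roc: empty input")
  stopifnot(ncol(patient_profiles) == ncol(control_loo_profiles))
  k <- ncol(patient_profiles)
  tpl <- colnames(patient_profiles)
  if (is.null(tpl)) tpl <- sprintf("template_%02d", seq_len(k))
  res <- lapply(seq_len(k), function(j) {
    pos <- patient_profiles[, j]; neg <- control_loo_profiles[, j]
    pos <- pos[is.finite(pos)]; neg <- neg[is.finite(neg)]
    auc <- auc_mann_whitney(pos, neg)
    orient <- if (auc >= 0.5) 1L else -1L
    s <- if (orient == 1L) 1 else -1
    list(auc = auc, auc_oriented = max(auc, 1 - auc), orientation = orient,
         curve = roc_points(s * pos, s * neg))
  })
  out <- data.frame(template = tpl,
                    auc = vapply(res, `[[`, numeric(1), "auc"),
                    auc_oriented = vapply(res, `[[`, numeric(1), "auc_oriented"),
                    orientation = vapply(res, `[[`, integer(1), "orientation"),
                    stringsAsFactors = FALSE)
  out$curve <- lapply(res, `[[`, "curve")
  out
}
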