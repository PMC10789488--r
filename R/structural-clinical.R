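#' Variance in functional co-localization explained by structure
#'
#' Per patient, the Spearman correlation across templates between the
#' functional (fALFF) and structural (GMV) Fisher-z co-localization profiles;
#' the median of those correlations, squared, is the fraction of variance in
#' the functional co-localization pattern explained by gray-matter volume.
#' Squaring discards the sign: perfectly anti-correlated profiles also give
#' a fraction of 1.
#'
#' @param falff_profiles,gmv_profiles Patients x templates Fisher-z matrices,
#'   aligned by patient and template (>= 3 templates).
#' @return List with `per_patient_r` (one Spearman rho per patient),
#'   `median_r`, and `fraction` = median(rho)^2.
#' @export
variance_explained <- function(falff_profiles, gmv_profiles) {
  falff_profiles <- as.matrix(falff_profiles)
  gmv_profiles <- as.matrix(gmv_profiles)
  stopifnot(identical(dim(falff_profiles), dim(gmv_profiles)))
  if (ncol(falff_profiles) < 3L) stop("variance_explained: need >= 3 templates")
  rs <- vapply(seq_len(nrow(falff_profiles)), function(i)
    spearman_rho(falff_profiles[i, ], gmv_profiles[i, ]), numeric(1))
  med <- stats::median(rs, na.rm = TRUE)
  list(per_patient_r = rs, median_r = med, fraction = med^2)
}

#' Clinical associations of co-localization strength
#'
#' Spearman correlation between each per-patient Fisher-z coefficient (one
#' column per template, typically the significant ones) and each clinical
#' score, with pairwise-complete deletion for missing scores and BH-FDR over
#' all (template, score) tests in the call.
#'
#' @param profiles Patients x templates Fisher-z matrix.
#' @param subject_table Data frame aligned with `profiles` rows, holding the
#'   score columns.
#' @param score_names Character vector of clinical score columns.
#' @return Data frame per (template, score): `rho`, `p`, `q`, `n` used.
#'   Scores with fewer than 5 complete pairs against every template are
#'   dropped with a warning.
#' @export
clinical_association <- function(profiles, subject_table, score_names) {
  profiles <- as.matrix(profiles)
  stopifnot(nrow(profiles) == nrow(subject_table))
  tpl <- colnames(profiles)
  if (is.null(tpl)) tpl <- sprintf("template_%02d", seq_len(ncol(profiles)))
  rows <- list()
  for (sc in score_names) {
    y <- subject_table[[sc]]
    if (is.null(y)) stop("clinical_association: no score column '", sc, "'")
    if (all(is.na(y))) {
      warning("clinical_association: score '", sc, "' is all-missing; excluded")
      next
    }
    for (j in seq_len(ncol(profiles))) {
      x <- profiles[, j]
      ok <- is.finite(x) & is.finite(y)
      n_ok <- sum(ok)
      if (n_ok < 5L) {
        warning("clinical_association: fewer than 5 complete pairs for '",
                sc, "' x ", tpl[j], "; excluded")
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        template = tpl[j], score = sc, rho = unname(ct$estimate),
        p = ct$p.value, n = n_ok, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(template = character(), score = character(),
                      rho = numeric(), p = numeric(), q = numeric(),
                      n = integer()))
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out[, c("template", "score", "rho", "p", "q", "n")]
}

#' Kruskal-Wallis site-homogeneity check
#'
#' Tests whether subject-level Fisher-z co-localization coefficients differ
#' across acquisition sites (tie-corrected H, chi-square p,
#' df = number of sites with data - 1).
#'
#' @param values Numeric vector of per-subject coefficients.
#' @param sites Factor/character vector of site labels, same length.
#' @return List with `H`, `df`, `p`.
#' @export
site_homogeneity_test <- function(values, sites) {
  stopifnot(length(values) == length(sites))
  ok <- is.finite(values) & !is.na(sites)
  sites <- factor(as.character(sites[ok]))
  values <- values[ok]
  if (nlevels(sites) < 2L) stop("site_homogeneity_test: need >= 2 sites with data")
  if (stats::sd(values) == 0)
    return(list(H = 0, df = nlevels(sites) - 1L, p = 1))
  kt <- stats::kruskal.test(values, sites)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}
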