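#' Donor expression set
#'
#' Regional gene-expression values per donor: a named list of
#' regions x genes matrices (one per donor) sharing region and gene order.
#' Missing donor-region values are `NA` and handled by pairwise deletion.
#'
#' @param donor_values Named list of regions x genes numeric matrices.
#' @param region_ids Optional region identifiers (rows).
#' @return Object of class `donor_expression_set`.
#' @export
donor_expression_set <- function(donor_values, region_ids = NULL) {
  stopifnot(is.list(donor_values), length(donor_values) >= 1L)
  g0 <- colnames(donor_values[[1]])
  d0 <- dim(donor_values[[1]])
  for (m in donor_values) stopifnot(identical(dim(m), d0), identical(colnames(m), g0))
  if (is.null(names(donor_values)))
    names(donor_values) <- sprintf("donor_%d", seq_along(donor_values))
  if (is.null(region_ids)) region_ids <- seq_len(d0[1])
  structure(list(donors = donor_values, region_ids = region_ids,
                 genes = g0), class = "donor_expression_set")
}

gene_column <- function(donor_set, gene) {
  if (!(gene %in% donor_set$genes))
    stop("gene '", gene, "' not present in the donor expression set")
  lapply(donor_set$donors, function(m) m[, gene])
}

#' Patient-level gene expression co-localization
#'
#' For each patient and each donor separately, the Spearman correlation
#' between the patient's regional z-map and the donor's regional expression
#' of the gene, Fisher z-transformed, then averaged over donors (donors
#' first, patients second). A one-sample t-test asks whether the per-patient
#' donor-averaged coefficients deviate from zero, Bonferroni-corrected for
#' the supplied gene list.
#'
#' @param zmaps Patients x regions matrix of regional z values.
#' @param donor_set A `donor_expression_set` aligned to the same regions.
#' @param genes Character vector of gene names (the Bonferroni family).
#' @return Data frame per gene: `mean_z`, `mean_r`, `t`, `df`, `p`,
#'   `p_bonferroni`, `significant` (at 0.05 after correction), plus a
#'   `patient_z` list-column of per-patient donor-averaged coefficients.
#' @export
patient_gene_coloc <- function(zmaps, donor_set, genes) {
  zmaps <- as.matrix(zmaps)
  stopifnot(ncol(zmaps) == length(donor_set$region_ids))
  m <- length(genes)
  rows <- lapply(genes, function(g) {
    expr <- gene_column(donor_set, g)
    per_pat <- vapply(seq_len(nrow(zmaps)), function(i) {
      zs <- vapply(expr, function(e) {
        ok <- is.finite(zmaps[i, ]) & is.finite(e)
        if (sum(ok) < 4L) return(NA_real_)
        r <- spearman_rho(zmaps[i, ok], e[ok])
        if (is.na(r)) NA_real_ else fisher_z(r)
      }, numeric(1))
      mean(zs, na.rm = TRUE)
    }, numeric(1))
    tt <- stats::t.test(per_pat, mu = 0)
    data.frame(gene = g, mean_z = mean(per_pat, na.rm = TRUE),
               mean_r = fisher_z_inv(mean(per_pat, na.rm = TRUE)),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, patient_z = I(list(per_pat)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(out$p * m, 1)
  out$significant <- out$p_bonferroni < 0.05
  rownames(out) <- NULL
  out
}

#' Template-level gene expression co-localization
#'
#' Per donor, the Spearman correlation between a neurotransmitter template's
#' regional means and the donor's regional expression of the gene, Fisher
#' z-transformed and averaged over donors.
#'
#' @param template_rv Template regional means.
#' @param donor_set A `donor_expression_set`.
#' @param gene Gene name.
#' @return List with `mean_z`, `mean_r`, and `donor_z` (per-donor values).
#' @export
template_gene_coloc <- function(template_rv, donor_set, gene) {
  expr <- gene_column(donor_set, gene)
  stopifnot(length(template_rv) == length(donor_set$region_ids))
  zs <- vapply(expr, function(e) {
    ok <- is.finite(template_rv) & is.finite(e)
    if (sum(ok) < 4L) return(NA_real_)
    r <- spearman_rho(template_rv[ok], e[ok])
    if (is.na(r)) NA_real_ else fisher_z(r)
  }, numeric(1))
  mz <- mean(zs, na.rm = TRUE)
  list(mean_z = mz, mean_r = fisher_z_inv(mz), donor_z = zs)
}

#' Gene differential stability across donors
#'
#' Fisher-z Spearman correlation of the gene's regional expression for every
#' donor pair (pairwise deletion of missing regions), averaged over pairs.
#' High values mean the expression pattern is robust across donors.
#'
#' @param donor_set A `donor_expression_set` with >= 2 donors.
#' @param gene Gene name.
#' @return List with `ds` (mean pairwise Fisher z), `ds_r` (back-transformed),
#'   and the `pairwise_z` matrix (upper triangle filled).
#' @export
gene_differential_stability <- function(donor_set, gene) {
  expr <- gene_column(donor_set, gene)
  n_d <- length(expr)
  if (n_d < 2L) stop("gene_differential_stability: need >= 2 donors")
  pz <- matrix(NA_real_, n_d, n_d, dimnames = list(names(expr), names(expr)))
  for (i in seq_len(n_d - 1L)) for (j in seq(i + 1L, n_d)) {
    r <- spearman_rho(expr[[i]], expr[[j]])
    pz[i, j] <- if (is.na(r)) NA_real_ else fisher_z(r)
  }
  vals <- pz[upper.tri(pz)]
  list(ds = mean(vals, na.rm = TRUE), ds_r = fisher_z_inv(mean(vals, na.rm = TRUE)),
       pairwise_z = pz)
}
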