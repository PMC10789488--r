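#' Pipeline configuration
#'
#' Settings for the end-to-end synthetic re-analysis. Analysis defaults match
#' the study: 1000 permutations for the cluster threshold, 10,000 for the
#' co-localization test, voxel p < 0.001, cluster p < 0.05, FDR q < 0.05,
#' GM-probability adjustment on.
#'
#' @param synthetic A [synthetic_config()] describing the generated inputs.
#' @param n_perm_cluster,n_perm_coloc Permutation counts.
#' @param voxel_p,cluster_p,fdr_q Thresholds.
#' @param adjust_gm Partial out regional GM probabilities in co-localization.
#' @param control_total_gmv Also run the fALFF co-localization with total GMV
#'   regressed out of the images.
#' @param clinical_target_rho Planted Spearman correlation between the
#'   patients' co-localization strength and the synthetic clinical score.
#' @param include_bold Exercise the BOLD -> fALFF spectral stage (reduced
#'   sizes) as part of the run.
#' @param genes Genes to simulate; `coupled_genes` names the subset whose
#'   latent pattern is the planted template.
#' @param seed Master seed; every stage derives its own stream from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            n_perm_cluster = 1000L, n_perm_coloc = 10000L,
                            voxel_p = 0.001, cluster_p = 0.05, fdr_q = 0.05,
                            adjust_gm = TRUE, control_total_gmv = TRUE,
                            clinical_target_rho = 0.4,
                            include_bold = FALSE,
                            genes = c("HTR1B", "HTR2A", "GABRB1", "SLC6A2",
                                      "GABRA1", "GABRG1"),
                            coupled_genes = c("HTR1B", "HTR2A"),
                            seed = 1L) {
  stopifnot(inherits(synthetic, "synthetic_config"),
            n_perm_cluster >= 100L, n_perm_coloc >= 100L,
            voxel_p > 0, voxel_p < 1, cluster_p > 0, cluster_p < 1,
            fdr_q > 0, fdr_q < 1, all(coupled_genes %in% genes))
  structure(list(synthetic = synthetic, n_perm_cluster = as.integer(n_perm_cluster),
                 n_perm_coloc = as.integer(n_perm_coloc), voxel_p = voxel_p,
                 cluster_p = cluster_p, fdr_q = fdr_q, adjust_gm = adjust_gm,
                 control_total_gmv = control_total_gmv,
                 clinical_target_rho = clinical_target_rho,
                 include_bold = include_bold, genes = genes,
                 coupled_genes = coupled_genes, seed = as.integer(seed)),
            class = "pipeline_config")
}

derive_seed <- function(seed, offset) as.integer((seed + 1000003 * offset) %% 2147483647)

#' Run the end-to-end synthetic analysis
#'
#' Generates every input (atlas, GM probability map, templates, fALFF-like
#' and GMV-like cohorts, clinical scores, expression donors), then executes
#' the analysis chain in study order: group contrasts with permutation-based
#' cluster inference, confound regression, co-localization with permutation
#' group tests and FDR (fALFF; GMV variant; total-GMV-controlled variant),
#' ROC discrimination, variance explained by structure, clinical
#' associations, site homogeneity, and the mRNA association / differential
#' stability analyses. All tables are written as TSV under `out_dir` together
#' with a run log of every derived seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created), or `NULL` to skip writing.
#' @return List of result tables and objects (class `pipeline_result`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sc <- config$synthetic
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  note("seed master ", config$seed)

  # --- synthetic inputs -----------------------------------------------------
  atl <- generate_atlas(sc$grid_shape, sc$n_regions, seed = derive_seed(config$seed, 1))
  note("seed atlas ", derive_seed(config$seed, 1))
  tpl <- generate_template_maps(atl, sc$n_templates, seed = derive_seed(config$seed, 2))
  note("seed templates ", derive_seed(config$seed, 2))
  set.seed(derive_seed(config$seed, 3))
  gm_map <- scalar_map(0.2 + 0.7 * stats::plogis(2 * smooth_noise_map(sc$grid_shape, 2)),
                       mask = atl$labels > 0L)
  gm_rv <- extract_regional_means(gm_map, atl)
  note("seed gm_map ", derive_seed(config$seed, 3))

  sc_falff <- sc; sc_falff$seed <- derive_seed(config$seed, 4)
  falff_cohort <- generate_cohort(atl, tpl, sc_falff)
  note("seed falff_cohort ", sc_falff$seed)
  sc_gmv <- sc; sc_gmv$seed <- derive_seed(config$seed, 5)
  sc_gmv$effect_size_beta <- 0  # structural arm carries no planted effect
  gmv_cohort <- generate_cohort(atl, tpl, sc_gmv)
  gmv_cohort$subjects <- falff_cohort$subjects  # same cohort, second modality
  note("seed gmv_cohort ", sc_gmv$seed)

  subjects <- falff_cohort$subjects
  is_pat <- subjects$group == "patient"
  covs <- intersect(names(sc$confound_effects), c("age", "sex", "site"))
  covs_gmv <- union(covs, "tiv")

  bold_summary <- NULL
  if (config$include_bold) {
    ts <- generate_bold(200L, 64L, tr_seconds = 2,
                        band_power_fraction = 0.5,
                        seed = derive_seed(config$seed, 6))
    note("seed bold ", derive_seed(config$seed, 6))
    reg <- cbind(build_friston24(ts$motion6), wm = ts$wm_signal, csf = ts$csf_signal)
    clean <- nuisance_regress_timeseries(ts, reg)
    bold_summary <- data.frame(n_voxels = nrow(ts$series), n_volumes = ncol(ts$series),
                               mean_falff = mean(compute_falff(clean)))
  }

  # --- group contrasts ------------------------------------------------------
  contrast_falff <- permutation_cluster_inference(
    falff_cohort$maps, subjects, covs, "control-patient",
    n_perm = config$n_perm_cluster, voxel_p = config$voxel_p,
    cluster_p = config$cluster_p, seed = derive_seed(config$seed, 7))
  note("seed contrast_falff ", derive_seed(config$seed, 7))
  contrast_gmv <- permutation_cluster_inference(
    gmv_cohort$maps, subjects, covs_gmv, "control-patient",
    n_perm = config$n_perm_cluster, voxel_p = config$voxel_p,
    cluster_p = config$cluster_p, seed = derive_seed(config$seed, 8))
  note("seed contrast_gmv ", derive_seed(config$seed, 8))

  # --- confound regression + regional extraction ----------------------------
  falff_clean <- regress_confounds_images(falff_cohort$maps, subjects, covs)
  gmv_clean <- regress_confounds_images(gmv_cohort$maps, subjects, covs_gmv)
  falff_rv <- extract_regional_means_cohort(falff_clean, atl)
  gmv_rv <- extract_regional_means_cohort(gmv_clean, atl)

  # --- co-localization ------------------------------------------------------
  coloc_falff <- coloc_group_test(
    falff_rv[is_pat, , drop = FALSE], falff_rv[!is_pat, , drop = FALSE],
    tpl$regional, gm_rv = gm_rv, adjust_gm = config$adjust_gm,
    n_perm = config$n_perm_coloc, seed = derive_seed(config$seed, 9))
  note("seed coloc_falff ", derive_seed(config$seed, 9))
  coloc_gmv <- coloc_group_test(
    gmv_rv[is_pat, , drop = FALSE], gmv_rv[!is_pat, , drop = FALSE],
    tpl$regional, gm_rv = gm_rv, adjust_gm = config$adjust_gm,
    n_perm = config$n_perm_coloc, seed = derive_seed(config$seed, 10))
  note("seed coloc_gmv ", derive_seed(config$seed, 10))

  coloc_falff_tgmv <- NULL
  if (config$control_total_gmv) {
    tb2 <- subjects
    tb2$total_gmv <- vapply(gmv_cohort$maps, function(m)
      sum(m$values[m$mask]), numeric(1))
    falff_clean2 <- regress_confounds_images(falff_cohort$maps, tb2,
                                             c(covs, "total_gmv"))
    rv2 <- extract_regional_means_cohort(falff_clean2, atl)
    coloc_falff_tgmv <- coloc_group_test(
      rv2[is_pat, , drop = FALSE], rv2[!is_pat, , drop = FALSE],
      tpl$regional, gm_rv = gm_rv, adjust_gm = config$adjust_gm,
      n_perm = config$n_perm_coloc, seed = derive_seed(config$seed, 11))
    note("seed coloc_falff_tgmv ", derive_seed(config$seed, 11))
  }

  # --- ROC ------------------------------------------------------------------
  loo_profiles <- coloc_profiles(falff_rv[!is_pat, , drop = FALSE], NULL,
                                 tpl$regional, gm_rv = gm_rv,
                                 adjust_gm = config$adjust_gm, loo = TRUE)
  roc <- coloc_roc(coloc_falff$profiles, loo_profiles)

  # --- variance explained + clinical + site ---------------------------------
  varexp <- variance_explained(coloc_falff$profiles, coloc_gmv$profiles)
  sig_templates <- coloc_falff$table$template[coloc_falff$table$q < config$fdr_q]
  planted_name <- if (!is.na(sc$planted_template_index))
    colnames(tpl$regional)[sc$planted_template_index] else NULL
  clin_template <- if (length(sig_templates)) sig_templates[1] else
    coloc_falff$table$template[which.min(coloc_falff$table$p)]
  strengths <- coloc_falff$profiles[, clin_template]
  pat_table <- subjects[is_pat, , drop = FALSE]
  pat_table <- generate_clinical(pat_table, strengths, config$clinical_target_rho,
                                 seed = derive_seed(config$seed, 12))
  note("seed clinical ", derive_seed(config$seed, 12))
  clin_profiles <- coloc_falff$profiles[, unique(c(sig_templates, clin_template)),
                                        drop = FALSE]
  clinical <- clinical_association(clin_profiles, pat_table, "clinical_score")
  site_test <- site_homogeneity_test(strengths, pat_table$site)

  # --- mRNA association -----------------------------------------------------
  coupling <- if (!is.null(planted_name))
    stats::setNames(rep(list(tpl$regional[, sc$planted_template_index]),
                        length(config$coupled_genes)), config$coupled_genes)
  donors <- generate_donors(atl, config$genes, coupling_templates = coupling,
                            inter_donor_rho = sc$inter_donor_rho,
                            n_donors = sc$n_donors,
                            seed = derive_seed(config$seed, 13))
  note("seed donors ", derive_seed(config$seed, 13))
  zmaps <- t(apply(falff_rv[is_pat, , drop = FALSE], 1, zscore_vs_controls,
                   control_rvs = falff_rv[!is_pat, , drop = FALSE]))
  mrna <- patient_gene_coloc(zmaps, donors, config$genes)
  tpl_gene <- do.call(rbind, lapply(config$genes, function(g) {
    tg <- template_gene_coloc(
      tpl$regional[, if (!is.null(planted_name)) sc$planted_template_index else 1L],
      donors, g)
    data.frame(gene = g, mean_z = tg$mean_z, mean_r = tg$mean_r)
  }))
  ds <- do.call(rbind, lapply(config$genes, function(g) {
    d <- gene_differential_stability(donors, g)
    data.frame(gene = g, ds_z = d$ds, ds_r = d$ds_r)
  }))

  result <- structure(list(
    config = config, atlas = atl, templates = tpl, gm_rv = gm_rv,
    subjects = subjects, patients = pat_table,
    contrast_falff = contrast_falff, contrast_gmv = contrast_gmv,
    coloc_falff = coloc_falff, coloc_gmv = coloc_gmv,
    coloc_falff_total_gmv = coloc_falff_tgmv,
    roc = roc, variance_explained = varexp, clinical = clinical,
    site_test = site_test, mrna = mrna, template_gene = tpl_gene,
    gene_stability = ds, bold_summary = bold_summary,
    ground_truth = falff_cohort$ground_truth, log = log_lines),
    class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(subjects, file.path(out_dir, "subjects.tsv"))
    write_tsv(coloc_falff$table, file.path(out_dir, "coloc_falff.tsv"))
    write_tsv(coloc_gmv$table, file.path(out_dir, "coloc_gmv.tsv"))
    if (!is.null(coloc_falff_tgmv))
      write_tsv(coloc_falff_tgmv$table, file.path(out_dir, "coloc_falff_total_gmv.tsv"))
    write_tsv(contrast_falff$clusters, file.path(out_dir, "clusters_falff.tsv"))
    write_tsv(contrast_gmv$clusters, file.path(out_dir, "clusters_gmv.tsv"))
    write_tsv(roc, file.path(out_dir, "roc.tsv"))
    write_tsv(clinical, file.path(out_dir, "clinical.tsv"))
    write_tsv(mrna, file.path(out_dir, "mrna.tsv"))
    write_tsv(tpl_gene, file.path(out_dir, "template_gene.tsv"))
    write_tsv(ds, file.path(out_dir, "gene_stability.tsv"))
    write_tsv(data.frame(
      key = c("variance_explained_fraction", "site_H", "site_df", "site_p"),
      value = c(varexp$fraction, site_test$H, site_test$df, site_test$p)),
      file.path(out_dir, "summary.tsv"))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
    write_tsv(data.frame(beta = falff_cohort$ground_truth$beta,
                         planted_template_index = falff_cohort$ground_truth$planted_template_index,
                         seed = falff_cohort$ground_truth$seed),
              file.path(out_dir, "ground_truth.tsv"))
  }
  result
}
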