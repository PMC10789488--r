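#!/usr/bin/env Rscript
# Stage 6: gene-expression association and differential stability.
#
# A 169-region expression arm with six synthetic donors: genes coupled to
# the planted template's spatial pattern (stand-ins for receptor-coding
# transcripts) and uncoupled control genes. Per patient and donor, Spearman
# correlations between the patient z-map and the donor's regional
# expression are Fisher z-transformed, averaged over donors, and tested
# against zero with Bonferroni correction over the gene list. Gene
# differential stability is the mean pairwise inter-donor Fisher-z Spearman.
#
# run from the repository root: Rscript analysis/06_mrna.R

library(neurocoloc)
source("analysis/settings.R")
dir.create(out_dir(), recursive = TRUE, showWarnings = FALSE)

# expression arm on its own finer parcellation
atl <- generate_atlas(c(14L, 14L, 14L), N_REGIONS_MRNA, seed = SEED_ATLAS + 1L)
tpl <- generate_template_maps(atl, N_TEMPLATES, smoothness = TEMPLATE_SMOOTHNESS,
                              seed = SEED_TEMPLATES + 1L)
cfg <- synthetic_config(grid_shape = c(14L, 14L, 14L), n_regions = N_REGIONS_MRNA,
                        n_templates = N_TEMPLATES, n_patients = N_PATIENTS,
                        n_controls = N_CONTROLS, planted_template_index = PLANTED,
                        effect_size_beta = BETA_PLANTED, noise_sd = NOISE_SD,
                        n_donors = N_DONORS, inter_donor_rho = INTER_DONOR_RHO,
                        seed = SEED_COHORT + 2L)
coh <- generate_cohort(atl, tpl, cfg)
clean <- regress_confounds_images(coh$maps, coh$subjects, COVARIATES)
rv <- extract_regional_means_cohort(clean, atl)
is_pat <- coh$subjects$group == "patient"
zmaps <- t(apply(rv[is_pat, ], 1, zscore_vs_controls,
                 control_rvs = rv[!is_pat, ]))

genes <- c("HTR1B", "HTR2A", "GABRB1", "SLC6A2", "GABRA1", "GABRG1")
coupled <- c("HTR1B", "HTR2A", "GABRB1")
coupling <- setNames(rep(list(tpl$regional[, PLANTED]), length(coupled)), coupled)
donors <- generate_donors(atl, genes, coupling_templates = coupling,
                          inter_donor_rho = INTER_DONOR_RHO,
                          n_donors = N_DONORS, seed = SEED_ANALYSIS + 5L)

mrna <- patient_gene_coloc(zmaps, donors, genes)
write_tsv(mrna, out_dir("mrna.tsv"))
cat("patient z-map x gene expression (donor-averaged, Bonferroni over",
    length(genes), "genes):\n")
print(mrna[, c("gene", "mean_r", "t", "p_bonferroni", "significant")],
      digits = 3, row.names = FALSE)

tpl_gene <- do.call(rbind, lapply(genes, function(g) {
  tg <- template_gene_coloc(tpl$regional[, PLANTED], donors, g)
  data.frame(gene = g, mean_z = tg$mean_z, mean_r = tg$mean_r)
}))
write_tsv(tpl_gene, out_dir("template_gene.tsv"))
cat("\nplanted template x gene expression (mean r over donors):\n")
print(tpl_gene, digits = 3, row.names = FALSE)

ds <- do.call(rbind, lapply(genes, function(g) {
  d <- gene_differential_stability(donors, g)
  data.frame(gene = g, ds_z = d$ds, ds_r = d$ds_r)
}))
write_tsv(ds, out_dir("gene_stability.tsv"))
cat("\ngene differential stability (mean pairwise inter-donor Fisher z):\n")
print(ds, digits = 3, row.names = FALSE)
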