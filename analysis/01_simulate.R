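#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# The study's raw data are not publicly available, so every input is
# simulated with known ground truth: a gray-matter atlas, eleven
# neurotransmitter-like template maps with bounded mutual correlation, a
# cohort of 52 patients and 22 controls whose patient maps carry a planted
# negative co-localization with one template (strength calibrated in stage
# 04), and realistic demographics. Volumes go to results/synthetic/ as NIfTI,
# tables as TSV. Later stages re-derive the same objects deterministically
# from the shared seed, so they do not depend on these files.

# run from the repository root: Rscript analysis/01_simulate.R
library(neurocoloc)
source("analysis/settings.R")

dir.create(out_dir("synthetic"), recursive = TRUE, showWarnings = FALSE)

atl <- generate_atlas(GRID, N_REGIONS, seed = SEED_ATLAS)
tpl <- generate_template_maps(atl, N_TEMPLATES, smoothness = TEMPLATE_SMOOTHNESS,
                              seed = SEED_TEMPLATES)
coh <- generate_cohort(atl, tpl, cohort_config(beta = BETA_PLANTED))

write_atlas_nifti(atl, file.path(out_dir("synthetic"), "atlas.nii.gz"))
for (k in seq_len(N_TEMPLATES))
  write_scalar_map_nifti(tpl$maps[[k]],
                         file.path(out_dir("synthetic"),
                                   sprintf("template_%02d.nii.gz", k)))
write_tsv(coh$subjects, file.path(out_dir("synthetic"), "subjects.tsv"))
write_tsv(data.frame(beta = coh$ground_truth$beta,
                     planted_template_index = coh$ground_truth$planted_template_index,
                     seed = coh$ground_truth$seed),
          file.path(out_dir("synthetic"), "ground_truth.tsv"))

cm <- abs(cor(tpl$regional, method = "spearman")); diag(cm) <- 0
cat("atlas:", atl$n_regions, "regions on a", paste(dim(atl$labels), collapse = "x"),
    "grid (", sum(atl$labels > 0), "GM voxels )\n")
cat("templates:", N_TEMPLATES, "; max pairwise regional |rho| =",
    round(max(cm), 3), "(cap 0.3)\n")
cat("cohort:", sum(coh$subjects$group == "patient"), "patients /",
    sum(coh$subjects$group == "control"), "controls; planted template",
    coh$ground_truth$planted_template_index, "at beta =",
    coh$ground_truth$beta, "\n")
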