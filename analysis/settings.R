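# Shared settings for the analysis stages. Every stage derives its inputs
# deterministically from these seeds, so stages can run independently.

GRID <- c(12L, 12L, 12L)
N_REGIONS <- 74L            # co-localization arm parcellation
N_REGIONS_MRNA <- 169L      # expression arm parcellation
N_TEMPLATES <- 11L
TEMPLATE_SMOOTHNESS <- 1.0
N_PATIENTS <- 52L
N_CONTROLS <- 22L
PLANTED <- 3L
BETA_PLANTED <- 0.65        # overwritten by the calibrated value where used
NOISE_SD <- 1
N_DONORS <- 6L
INTER_DONOR_RHO <- 0.5
CLINICAL_RHO <- 0.4

SEED_ATLAS <- 101L
SEED_TEMPLATES <- 102L
SEED_COHORT <- 103L
SEED_ANALYSIS <- 104L

COVARIATES <- c("age", "sex", "site")
N_PERM_CLUSTER <- 1000L
N_PERM_COLOC <- 10000L

out_dir <- function(...) file.path("results", ...)

cohort_config <- function(beta = BETA_PLANTED, seed = SEED_COHORT) {
  synthetic_config(grid_shape = GRID, n_regions = N_REGIONS,
                   n_templates = N_TEMPLATES, n_patients = N_PATIENTS,
                   n_controls = N_CONTROLS, planted_template_index = PLANTED,
                   effect_size_beta = beta, noise_sd = NOISE_SD,
                   n_donors = N_DONORS, inter_donor_rho = INTER_DONOR_RHO,
                   seed = seed)
}

# regenerate the shared objects (cheap and deterministic)
simulated_inputs <- function(beta = BETA_PLANTED) {
  atl <- generate_atlas(GRID, N_REGIONS, seed = SEED_ATLAS)
  tpl <- generate_template_maps(atl, N_TEMPLATES,
                                smoothness = TEMPLATE_SMOOTHNESS,
                                seed = SEED_TEMPLATES)
  coh <- generate_cohort(atl, tpl, cohort_config(beta = beta))
  list(atlas = atl, templates = tpl, cohort = coh)
}
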