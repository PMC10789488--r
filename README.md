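# neurocoloc

Spatial co-localization of functional brain alterations with
neurotransmitter density maps.

## What this package is for

In neurodegenerative disease, resting-state functional alterations are not
distributed at random: if a disease preferentially hits one neurotransmitter
system, activity loss should follow that system's spatial density. This
package implements the full analysis chain for testing that hypothesis in a
patient-control resting-state fMRI design, for researchers who want to run,
audit, or stress-test the method:

- **fALFF** (fractional amplitude of low-frequency fluctuations) from
  nuisance-cleaned BOLD series: the ratio of spectral amplitude inside
  0.01–0.08 Hz to the whole positive spectrum, per voxel, after regressing
  out Friston-24 motion and mean WM/CSF signals.
- **Voxel-wise group contrasts** (group + age, sex, site; TIV for
  volumetric maps) with an exact permutation-based cluster threshold
  (voxel p < 0.001, cluster p < 0.05, label permutations).
- **Co-localization**: per patient, the regional alteration pattern
  z = (patient − mean(HC)) / sd(HC) is correlated (Fisher-z Spearman,
  optionally partial with respect to regional gray-matter probability) with
  each reference density template T_k:

      ζ_ik = atanh( ρ(z_i, T_k) )

  The patient mean of ζ per template is tested against zero by re-assigning
  subjects to groups (z-maps re-derived per permutation), with BH-FDR over
  the template set; the reported mean r = tanh(mean ζ). Negative mean r
  means patients lose signal where density is high.
- **ROC discrimination** of patients from leave-one-out control z-maps by
  their coefficients (Mann-Whitney AUC, orientation flagged).
- **Structural and clinical context**: the GMV variant, the variance in the
  functional co-localization pattern explained by structure
  (median-across-patients correlation, squared), clinical-score
  associations with FDR, Kruskal-Wallis site homogeneity, and cluster
  eigenvariates.
- **Gene expression**: donor-wise Spearman correlations of patient z-maps
  with regional expression, Fisher-z averaged over donors, Bonferroni
  one-sample t-tests; gene differential stability as the mean pairwise
  inter-donor Fisher-z Spearman.
- **A synthetic-data module** that generates every input (atlas, templates,
  cohorts with planted effects, BOLD, donors, clinical scores) with known
  ground truth, including a Monte-Carlo calibration of the planted effect
  size to a target mean correlation.

The original cohort data are not publicly available, so the package ships
as an analysis workflow over synthetic data with planted, calibrated
effects: every stage's calibration and power are measured, not assumed.

## Worked example

Generate a study-sized synthetic cohort (52 patients, 22 controls, 74
regions, 11 templates) with an effect planted on template 3, then run the
core analysis:

```r
library(neurocoloc)

atl <- generate_atlas(c(12, 12, 12), 74, seed = 101)
tpl <- generate_template_maps(atl, 11, smoothness = 1, seed = 102)
cfg <- synthetic_config(grid_shape = c(12, 12, 12), n_regions = 74,
                        n_templates = 11, planted_template_index = 3,
                        effect_size_beta = 0.875, seed = 103)
coh <- generate_cohort(atl, tpl, cfg)

clean <- regress_confounds_images(coh$maps, coh$subjects, c("age", "sex", "site"))
rv <- extract_regional_means_cohort(clean, atl)
is_pat <- coh$subjects$group == "patient"

res <- coloc_group_test(rv[is_pat, ], rv[!is_pat, ], tpl$regional,
                        n_perm = 10000, seed = 104)
res
```

```
Co-localization permutation test (10000 permutations, 52 patients)
    template   mean_z   mean_r      p      q
 template_01  0.04190  0.04187 0.1573 0.2472
 template_02  0.05984  0.05977 0.0329 0.0724
 template_03 -0.19088 -0.18859 0.0001 0.0011
 template_04 -0.07250 -0.07237 0.0180 0.0498
 template_05 -0.03506 -0.03505 0.2680 0.3685
 template_06  0.04715  0.04712 0.1250 0.2291
 template_07  0.07032  0.07021 0.0181 0.0498
 template_08 -0.01757 -0.01757 0.5339 0.5873
 template_09  0.02360  0.02359 0.3535 0.4320
 template_10  0.00861  0.00861 0.7214 0.7214
 template_11  0.07425  0.07411 0.0121 0.0498
```

The planted template is recovered with mean r ≈ −0.19 (patients lose signal
where that template's density is high) at the permutation floor
p = 1/(10000+1) rounded to 1e-4, FDR-significant at q ≈ 0.001. The weaker
flags on templates 4, 7 and 11 are leaked associations through their
residual correlation with the planted map — see the methods vignette's
limitations section. Discriminability of patients from controls by this
coefficient:

```r
loo <- coloc_profiles(rv[!is_pat, ], NULL, tpl$regional, loo = TRUE)
coloc_roc(res$profiles, loo)[3, c("template", "auc", "auc_oriented", "orientation")]
```

```
    template       auc auc_oriented orientation
 template_03 0.1704545    0.8295455          -1
```

AUC 0.83 with negative orientation: patients sit below controls on the
coefficient, as planted.

## The analysis workflow

Numbered drivers under `analysis/` (run from the repository root, in order;
shared settings in `analysis/settings.R`; tables land in `results/`):

| stage | what it does |
| --- | --- |
| `01_simulate.R` | writes the synthetic inputs (atlas, templates, cohort; NIfTI + TSV) |
| `02_falff.R`    | BOLD → Friston-24/WM/CSF nuisance regression → fALFF, across planted band-power levels |
| `03_contrast.R` | permutation cluster inference: distributed planted effect and a focal-lesion recovery |
| `04_coloc.R`    | effect-size calibration to mean ρ = −0.2, fALFF / GMV / total-GMV-controlled co-localization, ROC |
| `05_structural_clinical.R` | variance explained by GMV, clinical associations, site homogeneity |
| `06_mrna.R`     | 169-region expression arm: patient-gene and template-gene co-localization, differential stability |

`run_pipeline(pipeline_config(...))` runs the same chain in one call and
writes every result table plus a run log of all derived seeds.

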