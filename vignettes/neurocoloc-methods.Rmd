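---
title: "Methods: co-localizing functional brain alterations with neurotransmitter density maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-localizing functional brain alterations with neurotransmitter density maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`neurocoloc` implements, end to end, a cross-modal analysis chain for
resting-state fMRI in a patient-control design: local activity (fALFF) maps
are contrasted between groups, each patient's regional alteration pattern is
expressed as a z-map relative to the control group, and the spatial
similarity of that pattern to reference neurotransmitter density templates
(and to regional gene expression) is quantified and tested by permutation.
Because the cohort data such a study rests on are typically not shareable,
the package pairs the analysis chain with a first-class synthetic-data
module that generates every input with known ground truth, so that each
stage's operating characteristics (null calibration, power, specificity,
family-wise error) are measurable rather than assumed.

## The measurement model

**fALFF.** For a voxel time series $x_t$ ($t = 1..T$, repetition time
$\Delta t$), after removing the mean (optionally also a linear trend), let
$a_f$ denote the Fourier amplitude (square root of periodogram power) at
positive frequency $f$. The fractional amplitude of low-frequency
fluctuations is

$$\mathrm{fALFF} = \frac{\sum_{f \in [0.01, 0.08]\,\mathrm{Hz}} a_f}
                        {\sum_{f > 0} a_f},$$

a unitless quantity in $[0, 1]$, invariant to rescaling and mean shifts of
the series. Band edges are inclusive; a voxel with zero total amplitude is
missing. Before the transform, mean white-matter and CSF signals and the
24-parameter motion expansion $[R_t, R_{t-1}, R_t^2, R_{t-1}^2]$ are
regressed out voxel-wise (`build_friston24()`,
`nuisance_regress_timeseries()`).

Two conventions circulate for the ratio: summed amplitudes (implemented as
the default, the convention of the resting-state toolbox lineage this chain
follows) and a ratio of root-mean-square amplitudes (`ratio = "rms"`). The
linear detrend is available (`detrend = TRUE`) but off by default: detrending
a finite sample of a pure in-band oscillation redistributes ramp amplitude
across the whole spectrum and biases the ratio visibly (about 8% for a
single-frequency series), so the default keeps the canonical demean-only
definition and leaves detrending as an explicit choice for drifting
acquisitions.

**Group contrasts.** Voxel-wise OLS of map value on group plus covariates
(age, sex, site; TIV for volumetric maps), with categorical covariates
dummy-coded against the lexicographically first level. The group t statistic
is assessed one-sided per contrast direction at an uncorrected voxel
threshold (default $p < 0.001$), and cluster-level multiplicity is
controlled by an exact permutation scheme: group labels are permuted
(covariate rows stay attached to their subjects), the thresholded map is
recomputed, and the null distribution of the maximum cluster size yields
$p = (1 + \#\{\text{perm max} \ge \text{observed}\})/(1 + n_{\text{perm}})$.
Connected components use 18-connectivity by default (6 and 26 available);
connectivity affects clustering only, never the t values. Permutations are
drawn against a canonical subject order (by `id` when present), so
reordering subject rows reproduces results exactly. Because labels alone are
permuted, covariates that correlate strongly with group are not re-fit under
the null (no Freedman-Lane refit) — a documented limitation of the scheme.

**Co-localization.** Regional means are extracted under a gray-matter
parcellation (regions with no eligible voxels are missing, never
zero-filled). Patient regional values are z-transformed against the control
group, $z_r = (x_r - \bar{c}_r)/s_{c,r}$ with the sample ($n-1$) SD; a zero
control SD makes the region missing. The co-localization coefficient of a
patient with template $k$ is the Fisher-z transformed Spearman correlation

$$\zeta_{ik} = \mathrm{atanh}\,\rho\!\left(z_i, T_k\right),$$

computed over jointly non-missing regions (at least 4), with $\rho$ clipped
to $|\rho| \le 1 - 10^{-6}$ so degenerate inputs stay finite. With
GM-probability adjustment, $\rho$ is the partial Spearman: all three vectors
are average-ranked and the rank residuals of $z$ and $T$ on the GM ranks are
Pearson-correlated. The group statistic per template is the patient mean
$\bar\zeta_k$; its null is built by randomly reassigning all subjects to
patient/control roles (group sizes preserved — the permutation literally
re-derives z-maps and profiles each time), two-sided p by the add-one
convention, Benjamini-Hochberg FDR across the template set, and the reported
mean r is $\tanh(\bar\zeta_k)$. Negative mean r means patients lose signal
where template density is high.

**ROC.** Controls enter the same coefficient space through leave-one-out
z-maps (each control z-scored against the remaining controls). The AUC per
template is the Mann-Whitney pair-counting statistic (ties half), reported
with an orientation flag so the discriminating direction is explicit.

**Structure and clinic.** The GMV arm repeats the chain on volumetric maps
with TIV added to the confounds. The variance in the functional
co-localization pattern explained by structure is the square of the median
(across patients) of the per-patient Spearman correlation between the fALFF
and GMV profile vectors across templates; squaring discards the sign, so
perfectly anti-correlated profiles also yield 1. Clinical associations are
Spearman correlations between per-patient coefficients (significant
templates) and score columns, pairwise-complete with reported n, BH-FDR over
the (template, score) family of one call. Site homogeneity uses the
tie-corrected Kruskal-Wallis H (all-tied data give H = 0 by convention).

**Gene expression.** Donor-level regional expression enters as a
donor-by-region-by-gene set. Per patient and donor, the Spearman correlation
between the patient z-map and the donor's expression of a gene is Fisher
z-transformed; averaging is over donors first, then the per-patient means
are tested against zero (one-sample t, Bonferroni over the supplied gene
list — the family is the gene list of one call, matching a screen-then-test
flow). Gene differential stability is the mean pairwise inter-donor Fisher-z
Spearman of the gene's regional pattern. All outputs are invariant to donor
order, and the donors-then-patients averaging order is fixed (the tanh
nonlinearity makes the order observable; a test guards it).

## The synthetic study

The generator reproduces the study conditions as defaults: 52 patients and
22 controls; patient age $\mathcal{N}(61.5, 10.0^2)$ years, control age
$\mathcal{N}(63.6, 11.9^2)$; sex frequencies 38/14 (patients) and 9/13
(controls); TIV $\mathcal{N}(1450, 130)$ ml; 11 template maps; 6 expression
donors. Acquisition sites default to 3: the original consortium had nine
centers, but with cohorts of a few dozen subjects nine site dummies
regularly produce sparse or collinear confound designs, so the default keeps
the confound structure representative without destabilizing the OLS fits.

Maps live on a small voxel grid (defaults $16^3$, $12^3$ in the reduced test
conditions) under an ellipsoidal "gray-matter" mask partitioned into regions
by k-means on voxel coordinates. Templates are Gaussian-smoothed white noise,
rectified to nonnegative by subtracting the in-mask minimum; candidate sets
are resampled (bounded retries) until every pairwise regional |Spearman| is
below a cap (default 0.3), so a planted effect is attributable to one map.
Subject maps follow

$$\text{map}_i = \text{baseline} - \beta\,[i \in \text{patients}]\,T_{p}
  + \textstyle\sum_c \gamma_c\, w_{ci}\, P_c + \varepsilon_i,$$

with a shared smooth baseline, per-confound smooth patterns $P_c$ scaled by
centered covariate values $w_{ci}$, the planted template $T_p$, and iid
voxel noise. The planted strength $\beta$ is not chosen directly: a
Monte-Carlo bisection (`calibrate_effect_size()`) finds the $\beta$ whose
mean patient-template Spearman equals a target (the study-scale value is
$-0.2$), and logs every evaluation. Clinical scores are generated through a
Gaussian copula on the normal scores of the co-localization strengths;
expression donors share a latent pattern (optionally a template's regional
pattern) with the mixing weight set through the bivariate-normal identity
$r = 2\sin(\pi\rho_s/6)$ so that `inter_donor_rho` is the population
*Spearman* between donors and $\mathrm{atanh}(\rho_s)$ is the population
value the differential-stability estimator recovers.

Synthetic BOLD is synthesized in the frequency domain with the expected
power share inside 0.01-0.08 Hz set exactly; note that fALFF is an
*amplitude* ratio, so a 50% power share corresponds to an expected fALFF
above 0.5 (the in-band bins are fewer and individually stronger) — the test
suite computes the exact expectation rather than conflating the two scales.
The pipeline plants its group effect directly in the subject maps rather
than routing it through BOLD synthesis; the spectral stage is exercised
separately (and in the pipeline's optional BOLD leg), because planting a
calibrated regional effect through a spectral route would entangle two
generators' noise models in every recovery measurement.

What the generator does not emulate: hemodynamics, scanner artifacts,
spatial autocorrelation of noise (voxel noise is iid; only baseline,
confound patterns and templates are smooth), inter-site intensity
differences beyond the planted confound patterns, anatomy, and realistic
region-size distributions. Passing recovery tests therefore show the
statistical machinery is calibrated and sensitive under a known generative
model — not that real acquisitions satisfy that model.

## Numerical choices

- Fisher transform clips at $|\rho| = 1 - 10^{-6}$; back-transforms use
  plain tanh.
- Ties get average ranks everywhere (Spearman, partial Spearman, AUC).
- Degenerate rank residuals in the partial correlation (residual SD below
  $10^{-10}$ of the rank SD) return missing, never zero.
- Voxels whose GLM residual variance is numerically zero relative to the
  data scale report t = 0.
- Permutation p-values always use the add-one convention and can never be 0.
- Confound regression centers the design so the fitted intercept is the
  grand mean, which is added back: the operation preserves means and is
  idempotent.
- The cluster-inference and co-localization permutation streams are seeded
  explicitly; the co-localization engine (compiled) and the pure-R reference
  path are tested for exact agreement on complete data, and the R path
  handles missing regions by pairwise deletion.
- The eigenvariate of a cluster is the first singular component of the
  column-centered subject-by-voxel matrix, unit variance, sign anchored to
  correlate nonnegatively with the cluster mean.
- Table-level two-sample statistics reconstructed from printed summaries use
  the pooled-variance t (Welch behind a flag) and the uncorrected Pearson
  chi-square, the conventions that reproduce the printed values.

## Test and acceptance problem sizes

The test suite measures operating characteristics at reduced sizes chosen to
keep the full suite in the tens of minutes on one core: null calibration of
the co-localization test with 500 replicate cohorts (20 patients, 10
controls, 60 regions, 500 permutations); planted-effect recovery with 100
replicates at 52/22 subjects, 74 regions, 11 templates, 1000 permutations
(the study used 10,000; fewer permutations only coarsens p resolution);
cluster-level family-wise error with 200 null replicates on a $16^3$ grid at
200 permutations; 1000 randomized oracle comparisons per statistical
primitive; 60 replicates per level for differential-stability recovery. The
analysis drivers under `analysis/` run the study-sized configuration (52/22,
11 templates, 10,000 permutations) once.

## Known limitations

- **Correlated templates share planted signal.** With the decorrelation cap
  at 0.3, a template whose regional pattern correlates with the planted one
  at $\rho_{T}$ genuinely co-localizes with the planted alteration at about
  $\rho_{T} \times \rho_{\text{planted}}$; a 52-patient permutation test
  reliably detects such leakage for $\rho_T$ near the cap. Off-target
  positives in recovery simulations are therefore real leaked associations,
  not miscalibration (the same simulations with $\beta = 0$ reject at well
  under the nominal rate). Tightening the cap much below 0.3 is not
  attainable by resampling at 74 regions, where the sampling SD of a
  pairwise regional Spearman is already $\approx 0.12$. This mirrors the
  interpretive reality of the real analysis: inter-correlated receptor maps
  cannot be fully disentangled by marginal tests.
- Patients share the control group as reference, so their z-maps (and hence
  their coefficients) are not independent across patients; the permutation
  test accounts for this by re-deriving z-maps per permutation, but the
  one-sample t-tests of the expression arm inherit the dependence, as in
  the original toolchain.
- The variance-explained statistic discards the sign of the
  function-structure association by construction.
- Group-label permutation without covariate refit can be anti-conservative
  when confounds correlate strongly with group; the generator draws
  covariates independently of group (age differs only in distribution), so
  the reported calibrations hold under that design.
- The GMV arm of the synthetic pipeline carries no planted structural
  effect, so its variance-explained fraction is near zero by design; the
  statistic's boundary behavior is tested separately.
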