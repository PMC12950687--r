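---
title: "Multi-kernel genomic and phenomic prediction for biomass-partitioning traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-kernel genomic and phenomic prediction for biomass-partitioning traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Biomass-partitioning traits of wheat — spike partitioning index (SPI, the
ratio of spike dry weight to above-ground biomass at anthesis + 7 days),
harvest index (HI, grain weight over biomass at maturity), fruiting
efficiency (FE, grains per gram of spike dry weight), grain number (GN,
grains per m²) and grain yield (GY, g m⁻²) — are expensive to phenotype:
they require destructive sampling, oven drying and threshing of plot
subsamples. Breeding programmes therefore want to predict them, either from
genome-wide markers (genomic prediction), from aerial hyperspectral
reflectance of the canopy (phenomic prediction), or from both plus
environmental information (multi-omic prediction).

`kernpred` implements that prediction stack end to end for multi-year
trials laid out as replicated alpha-lattices, together with a synthetic
trial generator so the whole pipeline can be exercised and tested without
field, genotyping or UAV data.

## The two-stage model

**Stage 1 (plot level).** Plot records are adjusted per environment with a
fixed-genotype linear mixed model,

$$y_{ijkl} = \mu + g_i + B_j + R_{k(j)} + C_{l(j)} + \beta\,\mathrm{DTA} + e_{ijkl},$$

with incomplete block \(B\), row \(R\) and column \(C\) random (REML via
lme4) and days to anthesis (DTA) as a fixed covariate to remove maturity
confounding. The genotype estimates are the per-environment BLUEs
(`blues_per_environment()`). A combined all-random model over environments
yields variance components and broad-sense heritability on an entry-mean
basis,

$$H^2 = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_{G\times E}/n + \sigma^2_e/(nr)},$$

with \(n\) environments and \(r\) replicates
(`reml_variance_components()`, `heritability()`).

**Stage 2 (genotype-environment level).** BLUEs \(y_{ij}\) are modelled
with a multi-kernel RKHS mixed model,

$$y_{ij} = \mu + E_j + g_i + h_{ij} + v_{ij} + w_j + gw_{ij} + e_{ij},$$

where each random term has a kernel covariance: the VanRaden genomic
relationship matrix \(G = WW'/2\sum p_k(1-p_k)\) expanded to observations
as \(ZGZ'\); the hyperspectral kernel \(H\), a centred/scaled cross-product
\(XX'/p\) of per-band adjusted means combined across environments; the
vegetation-index kernel \(V = SS'/n_\mathrm{indices}\) built from NDVI and
EVI at two timepoints; the environmental kernel \(W = MM'/Q\) built from
\(Q\) weekly environmental covariates; and the genotype-by-environment
interaction \(GW = Z_gGZ_g' \circ Z_EWZ_E'\) (Hadamard product, PSD by the
Schur product theorem). Any subset of terms defines a model; `G`, `H` and
the full `G+H+V+W+GW` are predefined in `standard_models()`.

### The Gibbs sampler

`fit_multikernel()` fits the stage-2 model by Gibbs sampling. Each kernel
is eigendecomposed once, \(K = U D U'\) (eigenvalues below
\(10^{-10}\lambda_{\max}\) dropped), and the term is reparameterised as
\(u = Ub\) with independent coefficients \(b_k \sim N(0, d_k\sigma^2_t)\).
Because the eigenvectors are orthonormal, one sweep updates all
coefficients of a term jointly in closed form — the sampler needs only two
matrix-vector products per term per sweep and handles hundreds of
observations in milliseconds per sweep. Fixed effects (intercept and
environment) carry flat priors; every variance has a scaled-inverse-χ²
prior with `df0 = 5` degrees of freedom and scale chosen so the prior mode
corresponds to a proportion `R2 = 0.5` of the response variance split
equally across terms — the usual convention for this model family. Masked
responses (cross-validation test records, the external trial) remain in
the model: they are imputed from the current linear predictor each sweep,
and their posterior-mean linear predictor is the reported prediction.
Defaults are 12,000 sweeps with 2,000 burn-in and thinning 5 for stored
variance samples; predictions accumulate over every post-burn-in sweep. A
variance can be pinned exactly (`fix_var`), which is how the test suite
checks the sampler against the closed-form single-kernel BLUP
\(\hat u = K(K+\lambda I)^{-1}(y - X\hat\beta)\), \(\lambda =
\sigma^2_e/\sigma^2_g\).

When a model predicts an environment with no training records (the
leave-one-year-out scheme), its fixed effect is taken as the mean of the
training-environment effects — environment-specific signal must then come
through the `W`/`GW` terms — and a message reports this.

### Machine-learning baselines

`fit_rfr()` (ranger regression forest, 100 trees, all predictors per
split, fixed seed) and `fit_plsr()` (NIPALS partial least squares with the
component count chosen by inner 5-fold cross-validation minimising MSE)
take kernel rows as features, concatenated per observation
(`ml_features()`), mirroring the common practice of left-joining
relationship-matrix rows on year and genotype.

## Validation schemes

* **CV2** (`run_cv2()`): random records masked in 5 folds; record-level
  folds for the BLUP engine, genotype-level folds for the ML engines.
* **CV0** (`run_cv0()`): a whole year left out; the remaining years are
  split in 5 folds and each rotation trains on 4 of them and predicts the
  entire held-out year; per-year predictive ability is summarised as mean
  ± sd over the 5 rotations.
* **External** (`run_external()`): a separate breeding trial is masked
  throughout; the training set is split in 5 folds, each 4-fold fit
  predicts the whole trial, and the 5 prediction vectors are averaged
  before computing predictive ability (per-fold values are also emitted).

Predictive ability is the Pearson correlation between predictions and
observations pooled over environments (`predictive_ability()`, with a
per-environment breakdown); selection skill is the coincidence index
(`coincidence_index()`), the percentage overlap of the top-k genotypes by
predicted and observed values (k = 30 by default, ties broken by stable
genotype order). Every scheme asserts train/test disjointness before any
fit.

## The synthetic trial generator

`simulation_config()` + `simulate_markers()` + `simulate_trial()` generate
a trial series with known ground truth. Defaults emulate a three-year
soft-wheat trial series with a separate 120-line validation trial, two
replicates in incomplete blocks of 20 plots, 273 hyperspectral bands from
398.47 to 1000.58 nm, five multispectral bands at two timepoints, and 11
weekly environmental covariates.

Key design choices, and what they do and do not emulate:

* **Traits via latent biomass.** Five base quantities are simulated
  directly (SPI, HI, GY, TGW and biomass at anthesis + 7 days, with means
  0.345, 0.355, 440 g m⁻², 28 g and 730 g m⁻² — typical published values
  for southern-US soft wheat) and the remaining traits follow from their
  algebraic identities (spike dry weight = SPI × biomass, GN =
  GY/(TGW/1000), FE = GN/spike dry weight, maturity biomass = GY/HI), so
  all five reported traits are mutually consistent on every plot and the
  identity-dependent code paths are testable. Ratio traits are kept inside
  (0, 1) by construction.
* **Genetics.** True genetic values are marker-driven, \(g = M\alpha\)
  with standard-normal marker effects, rescaled so the realised
  genotype-variance fraction matches the configured one exactly; default
  fractions follow typical multi-environment estimates for these traits
  (genotype 20–40%, G×E 10–20%). The genetic architecture (all markers
  contributing) is deliberately exposed as configuration rather than
  fixed, since trait-specific QTL architectures are unknown.
* **G×E structure.** A configurable share (`gxe_reaction_weight`, default
  0.25) of the interaction variance is a genotype-specific linear reaction
  to a 1-D environmental index computed from the EC matrix; the remainder
  is exchangeable marker-driven per-environment deviation. A purely 1-D
  reaction norm would concentrate all interaction in one environmental
  contrast and, with only three training years, make the combined-analysis
  ANOVA decomposition systematically disagree with the configured
  fractions by about half the G×E fraction; the blend keeps the interaction
  partly predictable from environmental covariates while making the
  configured fractions recoverable by REML.
* **Spectra.** Plot reflectance is a smooth green-canopy baseline plus
  Gaussian band loadings (negative at 670 nm, positive at 720 and 850 nm
  by default) carrying the standardised genetic and G×E signal of one
  trait (GY by default), plus AR(1) band noise (correlation 0.9, sd 0.008)
  mimicking smooth sensor noise — white noise would make L2 normalisation
  and kernel building unrealistically easy. HI deliberately has no
  spectral loading, reproducing the empirical pattern that hyperspectral
  kernels excel for yield-related traits while genomic kernels retain the
  advantage for HI. Multispectral band means are window averages of the
  hyperspectral bands; the second timepoint applies a fixed senescence
  decay per band.
* **Population structure.** Lines are near-fully inbred (dosage 0/2 with
  ~1% heterozygous calls); per-marker missingness and heterozygosity
  include a small fraction of pathological markers so the QC filters have
  real work. Validation genotypes are new marker realisations sharing the
  training marker-effect vectors — a weak stand-in for shared pedigree; no
  explicit pedigree is simulated. The generator does not emulate linkage
  disequilibrium, selection, population clusters, raw imagery, soil
  pixels, or multi-location same-year trials, so passing tests say nothing
  about those aspects of real data.

All randomness flows from one integer seed with fixed sub-stream offsets
per component, so any table can be regenerated bit-identically.

## Numerical choices

* Kernel feature scaling uses the population standard deviation (divisor
  n), so a single standardised column yields a unit mean diagonal; the
  convention is recorded in the kernel metadata. Zero-variance columns
  (e.g. region-wide dry weeks in the EC table) are dropped with a warning
  and `q` reduced accordingly.
* Kernels are accepted when the smallest eigenvalue is above
  \(-10^{-8}\lambda_{\max}\); anything lower aborts with the offending
  eigenvalue reported.
* QC thresholds are strict inequalities (missing fraction > 0.80, MAF
  < 0.05, heterozygosity > 0.10), attribution in that order; the missing
  threshold is unusually permissive but kept configurable and verbatim.
* Mean-dosage imputation stands in for haplotype-based imputation, which
  belongs to the upstream genotyping pipeline, not this package.
* Per-band and vegetation-index adjusted means use a multi-response OLS
  fit (genotype + DTA per environment) rather than 273 separate mixed
  models; with the small design variances of these trials this is the
  zero-random-variance limit of the trait BLUE model. Whether L2
  normalisation precedes or follows adjustment is configurable;
  normalise-then-adjust is the default.
* The DTA covariate is applied to all traits by default and is
  configurable per call; it enters as a single fixed slope (no
  genotype-by-DTA interaction).
* Coincidence-index ties are broken by stable genotype order; predictive
  ability returns `NA` with a warning when either vector is constant.

## Study sizes used by the tests

The test suite and acceptance script run the pipeline at desk scale: toy
kernels up to 5 × 6 for exact oracles; n = 60 and 20,000 sweeps for the
sampler-vs-closed-form check; 300 genotypes × 3 environments × 2
replicates for REML recovery (10 seeds) and residual-variance recovery (5
seeds); and 100 genotypes with 3,000 sweeps for the five-seed CV2
comparison of the G and H models. These sizes give stable medians while
keeping a full run in minutes.

## Known limitations

* The REML engine is lme4; degenerate designs fall back to OLS with a
  flag rather than failing.
* The sampler's variance partition is weakly identified when the genomic
  kernel has an unstructured (near-unrelated) eigenspectrum at small n —
  a property of the model, not the implementation; recovery tests use a
  structured population accordingly.
* CV1 (new genotypes within observed environments) is not implemented as
  a named scheme; spatial (AR1×AR1) adjustment and outlier screening are
  out of scope.
* The run-configuration layer (`read_run_config()`, `cmd_simulate()`,
  `cmd_run()`) is a function-level interface; there is no shell
  executable, as the package's functions and scripts are the intended
  entry points.
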