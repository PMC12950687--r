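Package: kernpred
Title: Multi-Kernel Genomic and Phenomic Prediction for Multi-Environment
    Wheat Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for kernel-based prediction of biomass-partitioning
    traits (spike partitioning index, harvest index, fruiting efficiency,
    grain number and grain yield) in multi-environment wheat trials.
    Implements marker quality control and the VanRaden genomic
    relationship matrix, L2 normalisation and vegetation indices for
    canopy reflectance, stage-1 mixed-model adjustment (REML variance
    components, broad-sense heritability, per-environment BLUEs with a
    days-to-anthesis covariate), construction of genomic (G),
    hyperspectral (H), vegetation-index (V), environmental-covariate (W)
    and Hadamard genotype-by-environment (GW) kernels, a multi-kernel
    Bayesian BLUP (RKHS) Gibbs sampler, random-forest and partial
    least-squares baselines, and CV2 / leave-one-year-out (CV0) /
    external-trial validation with predictive ability and coincidence
    index. A synthetic multi-environment trial generator with known
    ground truth supports end-to-end testing without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    ranger,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
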