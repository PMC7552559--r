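Package: telomereMR
Title: One-Sample Linear and Non-Linear Mendelian Randomization for
    Telomere Length and Ischemic Stroke
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for one-sample Mendelian randomization (MR) analysis of
    leukocyte telomere length (exposure, analysed on the natural-log scale)
    and ischemic stroke (binary outcome) in case-control data. Provides
    genotype encoding under five genetic models (over-dominant, dominant,
    recessive, co-dominant, additive), minor-allele-frequency and
    Hardy-Weinberg equilibrium computations, instrument validation against
    the three instrumental-variable assumptions, linear MR by the
    inverse-variance weighted, maximum likelihood and mode-based estimators,
    and semiparametric non-linear MR via stratified localized average causal
    effect (LACE) estimates with quadratic, Cochran's Q and fractional
    polynomial tests plus piecewise-linear and fractional-polynomial causal
    curves. A synthetic cohort generator reproduces the statistical
    structure of the motivating case-control study so that every pipeline
    stage is testable without access to individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
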