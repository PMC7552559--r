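---
title: "One-sample linear and non-linear Mendelian randomization for telomere length and ischemic stroke"
author: "telomereMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-sample linear and non-linear MR methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telomereMR)
```

## The causal question and the instrumental-variable model

Leukocyte telomere length (TL) shortens with biological aging and with many
stroke risk factors, so the observational TL-stroke association is open to
confounding and to reverse causation (stroke may itself accelerate telomere
attrition). Mendelian randomization sidesteps both by using germline variants
as instruments. A variant (or a genetic risk score, GRS) is a valid
instrument when it (1) is associated with TL, (2) is independent of
confounders of the TL-stroke relation, and (3) affects stroke risk only
through TL. The package operationalizes these as testable screens: a
control-only regression of ln TL on the coded genotype for (1); a covariate
screen (genotype against age, sex, smoking, drinking, BMI, blood pressures,
glucose, lipids, apolipoproteins) for (2) and, partially, (3). Assumption (3)
is not fully testable; the screen only bounds the risk of detectable
pleiotropy.

All exposure effects are on the natural-log scale: ln TL in ln-kb. Working on
the log scale makes genotype effects interpretable as percentage differences
in TL, `(exp(beta) - 1) * 100`, and makes the causal estimand "per
10% decrease in TL" a fixed shift of `ln 0.9` in the exposure.

Instrument-TL associations (and the covariate screen) are estimated in
controls only. In a case-control sample the cases are over-represented;
any downstream effect of disease on TL or on the biomarker covariates would
contaminate genotype-phenotype associations estimated in cases, whereas the
control group approximates the disease-free population.

### Genetic models

The principal genotype coding is over-dominant (heterosis): heterozygotes
coded 1 against both homozygote classes, matching the observed pattern at the
two instruments used in the motivating study, where heterozygotes carry
shorter telomeres than either homozygote group. Dominant, recessive,
co-dominant (two indicator contrasts) and additive codings are available for
subsidiary analyses. The GRS used for non-linear MR is the unweighted count
of TL-lowering (heterozygous) genotypes across instruments, range `0..J`.

## Linear MR

Each instrument contributes a summary pair: `beta_x` (mean ln TL difference
per coded genotype, controls only, unadjusted by default) and `beta_y`
(log-odds of stroke per coded genotype from a covariate-adjusted logistic
regression in the full sample). The per-instrument ratio estimate is
`theta_j = beta_y_j / beta_x_j`, with first-order delta-method standard error
`se_y_j / |beta_x_j|` (a second-order option adds the first-stage variance
term, relevant for weak instruments).

- **IVW**: fixed-effect inverse-variance weighted mean of the `theta_j`;
  algebraically the zero-intercept weighted least-squares slope of `beta_y`
  on `beta_x` with weights `se_y^-2`.
- **Maximum likelihood**: `beta_x_j ~ N(xi_j, se_x_j^2)`,
  `beta_y_j ~ N(theta xi_j, se_y_j^2)` jointly maximized over
  `(xi_1..xi_J, theta)`. Given `theta` the `xi_j` have a closed form, so the
  profile over `theta` is optimized numerically (Brent on a bracket around
  the IVW start); the SE comes from the observed information at the optimum.
  When first-stage uncertainty vanishes the estimator collapses to IVW,
  which the tests assert.
- **Mode-based**: the mode of an inverse-variance weighted normal-kernel
  density over the `theta_j`; bandwidth is a modified Silverman rule,
  `0.9 min(sd, mad) J^{-1/5}`, times a user factor (default 1). The mode is
  found by a 2001-point grid scan refined by golden-section search, and the
  interval by a seeded parametric bootstrap (default 1000 draws of
  `theta_j* ~ N(theta_j, se_j)`, percentile interval). With two instruments
  the mode is statistically degenerate; it is still computed, flagged, and
  warned about, because the motivating design has exactly two instruments.

Reporting uses `OR = exp(theta ln 0.9)` per 10% TL decrease: a 10% decrease
multiplies TL by 0.9 and therefore shifts ln TL by `ln 0.9`. The reciprocal
reading (a decrease undone by a 10/9-fold increase) is available as an
option; the package defaults to the multiplicative-0.9 convention and labels
it in output.

One open choice in one-sample MR is which stage carries the covariate
adjustment. The package defaults to an unadjusted control-only exposure stage
and a fully adjusted outcome stage, and records `adjusted_for` in every
result so both variants are reproducible; the exposure stage accepts
covariates when the analyst prefers symmetric adjustment.

## Non-linear MR

The semiparametric approach stratifies on the *IV-free exposure*: the
residual of ln TL after regressing out the GRS. Stratifying on raw exposure
would condition on a consequence of the instrument and induce collider bias;
residual stratification keeps the instrument-outcome relation intact within
strata. The residual regression is fit on all subjects by default (a
controls-only fit is available), and K defaults to 5 — displayed as exposure
quintiles — configurable between 2 and 10.

Within stratum k, `beta_x_k` (GRS on ln TL, unadjusted) and `beta_y_k` (GRS
on stroke, covariate-adjusted logistic) give the localized average causal
effect `LACE_k = beta_y_k / beta_x_k`, the local slope of the causal curve
`h(x)`. `beta_x_k` is re-estimated within each stratum by default (a
shared first-stage variant is a documented alternative; within-stratum
estimation lets instrument strength vary across the exposure range). Three
tests interrogate the LACE profile:

- **Quadratic test** — weighted least-squares trend of `LACE_k` on the
  stratum mean exposure, slope tested against zero with the variance from the
  weighted information matrix (stratum variances treated as known, as in
  fixed-effect meta-regression); a non-zero trend is the signature of
  curvature.
- **Cochran's Q** — `sum w_k (LACE_k - weighted mean)^2 ~ chi2(K-1)` under a
  constant causal slope; an omnibus heterogeneity test, sensitive to any
  departure, not only monotone curvature.
- **Fractional polynomial test** — for each power p in
  `{-2, -1, -0.5, 0, 0.5, 1, 2, 3}` the degree-1 curve `c G_p(x)` implies the
  derivative model `LACE_k = c x_k^{p-1}` (power 0 is the logarithmic curve,
  derivative `1/x`); each one-parameter model is fit by weighted Gaussian
  likelihood, the best power is selected, and twice the log-likelihood gain
  over the linear model (power 1, constant LACE) is referred to chi-squared
  with 1 df. Power-selection multiplicity is deliberately ignored, following
  the reference semiparametric method; this makes the test mildly
  anti-conservative, which the calibration experiment below quantifies.
  Exposures here are ln-kb and positive; if any stratum mean were
  non-positive a shift of `1 - min` is applied and recorded.

Causal curves are reconstructed two ways, both anchored at a reference
exposure (default: the stratum-size-weighted mean): a piecewise-linear curve
integrating each stratum's constant slope across contiguous segments
(segment boundaries are midpoints between consecutive stratum mean
exposures, since residual-defined strata overlap in raw exposure), with
pointwise variance accumulating squared segment lengths times LACE
variances; and the fractional-polynomial curve `c (G_p(x) - G_p(ref))` with
a delta-method band on `c`.

## The synthetic cohort generator

No individual-level data accompany the motivating study, so
`simulateCohort()` generates cohorts with the statistical structure the
analysis assumes, and the defaults of `studySimulationConfig()` encode the
study conditions: 431 cases and 304 controls; the two instruments with their
observed control-group minor allele frequencies (0.184 and 0.337) and
published over-dominant effects on ln TL (-0.108 and -0.089); ln TL centred
at `ln(6.7)` with residual SD 0.30 (matching the reported median 6.7 kb and
interquartile spread on the log scale); a covariate panel loosely targeting
the reported marginals (ages near 52 +/- 12, about half male, a third
smokers, BMI near 25, and so on) with small effects on exposure and outcome;
and a configurable causal shape, defaulting to "null" — the study's
conclusion. Case-control sampling is by rejection from the population model
(capped at 10^7 draws), which preserves the population genotype-exposure
joint distribution among controls — exactly what control-only instrument
estimation assumes. Covariates are mutually independent by default (the
study reports no dependence structure); a correlation matrix for the latent
Gaussian draws is accepted via Cholesky construction.

What the generator does *not* emulate: linkage disequilibrium between SNPs
(instruments are treated as independent, as the analysis assumes),
population stratification, covariate dependence (unless supplied),
measurement error in the qPCR TL assay, and the reported covariate marginals
beyond loose targets. Passing tests therefore demonstrate correctness of the
estimators under the assumed data-generating model, not robustness to those
real-data features.

Causal shapes are minimal forms distinguishing the three tests: linear
`theta x`, quadratic `theta x + theta2 x^2`, threshold
`theta max(0, x - c)`. Genotype effects are over-dominant by default with an
additive option for estimator stress tests.

## Numerical choices and edge cases

- Confidence intervals use the 1.96 normal quantile throughout, matching the
  convention under which standard errors are recovered from published
  intervals as `(high - low) / (2 * 1.96)`.
- The exact Hardy-Weinberg test is the default (conditional distribution of
  the heterozygote count given allele counts, summing probabilities no larger
  than the observed configuration's); the published control-group
  Hardy-Weinberg p-values of 1.000 at near-perfect fit are characteristic of
  the exact test, whereas the chi-squared test gives 0.905 there. Both are
  provided. Monomorphic SNPs get p = 1 with a warning.
- Odds-ratio intervals use the Woolf log-OR method; back-computation of the
  published instrument intervals (0.580-1.120, 0.660-1.190) matches Woolf at
  two decimals. Zero cells get a flagged 0.5 continuity correction.
- Instruments with `beta_x = 0` are rejected from ratio-based estimators with
  a message; a constant-response regression returns effect 0 with p = 1
  rather than NaN; quasi-complete separation and non-convergence in logistic
  stages are flagged, never silently replaced.
- Quantile stratification ranks with stable tie-breaking so group sizes
  differ by at most one; K exceeding the number of distinct values is an
  error. Strata lacking both outcome classes or with constant GRS are
  excluded from the tests with the degrees of freedom adjusted.
- Descriptive statistics follow a per-group Shapiro-Wilk rule at alpha 0.05
  (groups above the test's 5000-observation limit are thinned
  deterministically); quartiles use linear interpolation (R type 7); the
  Mann-Whitney test uses the normal approximation with tie correction.
- Two-sided p-values at alpha 0.05 everywhere, with no multiplicity
  correction at any stage, including the pleiotropy screen.

## Calibration and problem sizes

The test suite validates the machinery at sizes chosen to balance
Monte-Carlo resolution against runtime. Parameter recovery uses cohorts of
4,000-20,000 subjects (25-30 replicates, agreement within 3 Monte-Carlo
SEs); interval coverage uses 500 summary-level replicates with 10
instruments (IVW and ML coverage within 93-97%); the non-linearity tests
are calibrated under a linear causal mechanism at K = 5 with n = 5,000 per
replicate over 200 replicates (all three tests reject at 3.5-7.5% at
alpha = 0.05 in the shipped configuration) and powered under a strong
quadratic alternative at n = 20,000 (quadratic-test power above 0.95, and
the curvature-directed quadratic and fractional-polynomial tests reject more
often than the omnibus Q test). Determinism is asserted by byte-comparing
two runs of the full pipeline at a fixed seed.

## Known limitations

- Two instruments make the mode-based estimator degenerate (it is computed
  with a warning) and leave the fractional-polynomial machinery dependent on
  the GRS rather than per-SNP ratios.
- Ratio estimates from logistic outcome stages inherit the non-collapsibility
  of the odds ratio: with strong effects and large residual exposure
  variance the combined estimate is mildly attenuated relative to the
  conditional parameter. At the effect sizes and variances simulated here the
  attenuation is well inside Monte-Carlo noise.
- The pleiotropy screen controls only detectable pleiotropy; exclusion
  restriction remains an assumption.
- Instrument selection at the motivating sample size (304 controls) has
  limited power for exposure effects near -0.1 ln-kb, so selection outcomes
  vary across simulated replicates; analyses that fix the instrument set
  (as the original design did after validation) are exposed directly through
  `summaryAssociations()` and friends.
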