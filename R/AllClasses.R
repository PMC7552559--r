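#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats as.formula coef complete.cases chisq.test dnorm glm lm
#'   mad median optimHess optimize pchisq pnorm qnorm quantile rbinom rnorm
#'   runif sd setNames shapiro.test t.test vcov wilcox.test binomial plogis
#'   residuals fitted
#' @importFrom utils read.delim write.table head
NULL

#' Case-control cohort with genotypes, exposure and covariates
#'
#' `MRCohort` extends [SummarizedExperiment::SummarizedExperiment] to hold a
#' case-control Mendelian-randomization dataset: a SNP-by-subject genotype
#' assay coded as alternate-allele counts (0/1/2, `NA` for missing), subject
#' phenotypes in `colData` (binary `outcome`, 1 = case; continuous `exposure`
#' on the natural-log scale, here ln telomere length in ln-kb; plus named
#' covariates), and per-SNP metadata in `rowData` (`snp_id`, `chromosome`,
#' `gene`, `ref_allele`, `alt_allele`).
#'
#' @slot .. inherits all slots from `SummarizedExperiment`.
#' @seealso [MRCohort()] for construction, [caseStatus()], [exposureValues()],
#'   [genotypeMatrix()], [covariateData()], [snpInfo()] for access.
#' @export
setClass("MRCohort", contains = "SummarizedExperiment")

setValidity("MRCohort", function(object) {
  msg <- character()
  if (!"genotype" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'genotype' is required")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("outcome", "exposure") %in% colnames(cd))) {
    msg <- c(msg, "colData must contain 'outcome' and 'exposure'")
  } else {
    y <- cd$outcome
    if (!all(y %in% c(0L, 1L)))
      msg <- c(msg, "outcome must be binary 0/1 with no missing values")
    x <- cd$exposure
    if (any(!is.na(x) & !is.finite(x)))
      msg <- c(msg, "non-missing exposure values must be finite")
  }
  g <- SummarizedExperiment::assay(object, "genotype")
  if (!all(g %in% c(0L, 1L, 2L, NA)))
    msg <- c(msg, "genotypes must be alternate-allele counts 0/1/2 or NA")
  if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic case-control cohort generator
#'
#' Describes the population model from which case-control data are drawn:
#' biallelic SNPs in Hardy-Weinberg equilibrium with per-SNP over-dominant (or
#' additive) effects on the ln-scale exposure, mutually independent covariates
#' with linear effects on the exposure and on the outcome log-odds, and a
#' logistic outcome whose dependence on the exposure follows a configurable
#' causal shape.
#'
#' @slot nCases,nControls target numbers of cases and controls retained.
#' @slot snps data.frame with columns `snp_id`, `maf`, `delta` (genotype
#'   effect on the ln exposure) and `geneticModel` ("overdominant" applies
#'   `delta` to heterozygotes; "additive" applies `delta` per allele).
#' @slot exposureMean,exposureSd mean and residual SD of the ln exposure
#'   (ln-kb for ln telomere length).
#' @slot covariates data.frame with columns `name`, `type` ("continuous" or
#'   "binary"), `mean`, `sd` (continuous), `prob` (binary), `betaExposure`,
#'   `betaOutcome`; effects apply to mean-centred covariate values.
#' @slot covariateCor optional correlation matrix for the latent Gaussian
#'   draws behind the covariates (identity = independent, the default).
#' @slot causalShape one of "null", "linear", "quadratic", "threshold".
#' @slot theta,theta2,threshold causal parameters: linear is `theta * x`,
#'   quadratic adds `theta2 * x^2`, threshold is `theta * pmax(0, x - threshold)`.
#' @slot baselineLogOdds intercept of the outcome logistic model.
#' @slot seed integer RNG seed recorded with the simulated cohort.
#' @seealso [SimulationConfig()], [simulateCohort()], [studySimulationConfig()]
#' @export
setClass("SimulationConfig",
  representation(
    nCases = "integer", nControls = "integer",
    snps = "data.frame",
    exposureMean = "numeric", exposureSd = "numeric",
    covariates = "data.frame",
    covariateCor = "matrix",
    causalShape = "character",
    theta = "numeric", theta2 = "numeric", threshold = "numeric",
    baselineLogOdds = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nCases < 1L || object@nControls < 1L)
    msg <- c(msg, "nCases and nControls must be positive")
  s <- object@snps
  need <- c("snp_id", "maf", "delta", "geneticModel")
  if (!all(need %in% colnames(s)))
    msg <- c(msg, sprintf("snps needs columns %s", paste(need, collapse = ", ")))
  else {
    if (any(s$maf < 0 | s$maf > 1)) msg <- c(msg, "MAF must lie in [0, 1]")
    if (anyDuplicated(s$snp_id)) msg <- c(msg, "duplicate snp_id")
    if (!all(s$geneticModel %in% c("overdominant", "additive")))
      msg <- c(msg, "geneticModel must be 'overdominant' or 'additive'")
  }
  if (!is.finite(object@exposureSd) || object@exposureSd <= 0)
    msg <- c(msg, "exposureSd must be positive")
  if (!object@causalShape %in% c("null", "linear", "quadratic", "threshold"))
    msg <- c(msg, "unknown causalShape")
  if (!all(is.finite(c(object@theta, object@theta2, object@threshold,
                       object@baselineLogOdds))))
    msg <- c(msg, "causal shape parameters must be finite")
  k <- nrow(object@covariates)
  if (k && !identical(dim(object@covariateCor), c(k, k)))
    msg <- c(msg, "covariateCor must be a square matrix matching covariates")
  if (length(msg)) msg else TRUE
})

#' Linear Mendelian-randomization estimate
#'
#' Result of one of the linear MR estimators (inverse-variance weighted,
#' maximum likelihood, mode-based). `theta` is the causal log-odds of the
#' outcome per unit increase in the ln exposure; `orPer10` rescales it to the
#' odds ratio per 10 percent decrease in (untransformed) exposure.
#'
#' @slot method "ivw", "ml" or "mbe".
#' @slot theta,se point estimate and standard error on the log-odds scale.
#' @slot ci length-2 numeric, 95 percent confidence interval for `theta`.
#' @slot orPer10 odds ratio per 10 percent exposure decrease.
#' @slot orCI its 95 percent confidence interval.
#' @slot nInstruments number of instruments combined.
#' @slot diagnostics list: convergence flag, bootstrap replicates, warnings.
#' @export
setClass("MREstimate",
  representation(
    method = "character", theta = "numeric", se = "numeric",
    ci = "numeric", orPer10 = "numeric", orCI = "numeric",
    nInstruments = "integer", diagnostics = "list"
  )
)

setValidity("MREstimate", function(object) {
  msg <- character()
  if (length(object@ci) != 2L || (all(is.finite(object@ci)) && diff(object@ci) < 0))
    msg <- c(msg, "ci must be an ordered pair")
  if (is.finite(object@orPer10) && object@orPer10 <= 0)
    msg <- c(msg, "orPer10 must be positive")
  if (length(msg)) msg else TRUE
})

#' Semiparametric non-linear MR report
#'
#' Holds the per-stratum localized average causal effect (LACE) estimates, the
#' three non-linearity tests (quadratic trend, Cochran's Q, fractional
#' polynomial) and the reconstructed causal curves.
#'
#' @slot strata data.frame: one row per stratum (k, n, x_mean, x_low, x_high,
#'   beta_x, se_x, beta_y, se_y, lace, se_lace).
#' @slot tests data.frame: test, statistic, df, p_value.
#' @slot curves list of data.frames (`piecewise`, `fracpoly`) with columns
#'   x, effect, ci_low, ci_high.
#' @slot K number of strata requested.
#' @slot bestPower fractional-polynomial power selected for the curve.
#' @slot shift positivity shift applied to stratum means (0 if none).
#' @export
setClass("NonlinearMR",
  representation(
    strata = "data.frame", tests = "data.frame", curves = "list",
    K = "integer", bestPower = "numeric", shift = "numeric"
  )
)

#' Pipeline run configuration
#'
#' Either a simulation block or paths to a phenotype table and genotype file
#' (TSV or VCF); plus the candidate SNP list, genetic model, covariate list,
#' QC thresholds, stratification and bootstrap settings, and the run seed.
#'
#' @slot simulation a [SimulationConfig] or NULL (list of length 0 or 1).
#' @slot phenotypePath,genotypePath input paths ("" when simulating).
#' @slot candidateSnps character vector of SNP ids to consider as instruments.
#' @slot geneticModel genetic model for instrument coding.
#' @slot covariates covariate names used for outcome-model adjustment and the
#'   pleiotropy screen.
#' @slot thresholds named list: `maf_min`, `hwe_alpha`, `exposure_alpha`,
#'   `screen_alpha`.
#' @slot K number of exposure strata for non-linear MR.
#' @slot nBoot bootstrap replicates for the mode-based estimator.
#' @slot seed integer seed governing every stochastic stage.
#' @export
setClass("RunConfig",
  representation(
    simulation = "list",
    phenotypePath = "character", genotypePath = "character",
    candidateSnps = "character", geneticModel = "character",
    covariates = "character", thresholds = "list",
    K = "integer", nBoot = "integer", seed = "integer"
  )
)

setValidity("RunConfig", function(object) {
  msg <- character()
  hasSim <- length(object@simulation) == 1L
  hasPaths <- nzchar(object@phenotypePath) && nzchar(object@genotypePath)
  if (hasSim == hasPaths)
    msg <- c(msg, "exactly one of simulation / input paths must be given")
  if (hasSim && !is(object@simulation[[1L]], "SimulationConfig"))
    msg <- c(msg, "simulation must hold a SimulationConfig")
  if (!object@geneticModel %in% geneticModels())
    msg <- c(msg, "unknown genetic model")
  need <- c("maf_min", "hwe_alpha", "exposure_alpha", "screen_alpha")
  if (!all(need %in% names(object@thresholds)))
    msg <- c(msg, sprintf("thresholds needs %s", paste(need, collapse = ", ")))
  if (object@K < 2L) msg <- c(msg, "K must be at least 2")
  if (length(msg)) msg else TRUE
})
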