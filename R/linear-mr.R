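#' Instrument-outcome association
#'
#' Logistic regression of case status on the encoded genotype, in the full
#' sample, adjusting for covariates (the motivating analysis adjusts the
#' outcome stage for age, sex, smoking, drinking, BMI, blood pressures,
#' glucose and lipids).
#'
#' @inheritParams exposureAssociation
#' @param covariates covariate names to adjust for.
#' @return data.frame as in [exposureAssociation()] but with `effect` a
#'   log-odds ratio; `separation` flags suspected quasi-complete separation or
#'   non-convergence.
#' @export
outcomeAssociation <- function(cohort, snp, model = "overdominant",
                               covariates = character(),
                               effectAllele = "alt") {
  code <- encodedSNP(cohort, snp, model, effectAllele)
  out <- assocFit(caseStatus(cohort), code,
                  covariateData(cohort)[, covariates, drop = FALSE],
                  family = binomial(), minN = 20L)
  if (any(out$separation))
    warning(sprintf("possible separation/non-convergence for %s", snp))
  cbind(snp_id = snp, out, model = model, stringsAsFactors = FALSE)
}

#' Per-instrument summary associations for one-sample MR
#'
#' Computes, for each instrument, the exposure association (controls only,
#' unadjusted by default) and the outcome association (full sample, covariate
#' adjusted), under a common genetic coding — the (beta_x, se_x, beta_y, se_y)
#' pairs that the linear MR estimators combine.
#'
#' @inheritParams exposureAssociation
#' @param snps instrument SNP ids.
#' @param outcomeCovariates covariates adjusted for in the outcome stage.
#' @param exposureCovariates covariates adjusted for in the exposure stage
#'   (none by default; the control-only exposure regressions of the motivating
#'   analysis are reported unadjusted).
#' @return data.frame with columns `snp_id`, `beta_x`, `se_x`, `beta_y`,
#'   `se_y`, and attribute `adjusted_for` (outcome-stage covariates).
#' @export
summaryAssociations <- function(cohort, snps, model = "overdominant",
                                outcomeCovariates = character(),
                                exposureCovariates = character(),
                                effectAllele = "alt") {
  rows <- lapply(snps, function(s) {
    ex <- exposureAssociation(cohort, s, model, exposureCovariates,
                              effectAllele = effectAllele)
    oc <- outcomeAssociation(cohort, s, model, outcomeCovariates,
                             effectAllele = effectAllele)
    data.frame(snp_id = s, beta_x = ex$effect[1L], se_x = ex$se[1L],
               beta_y = oc$effect[1L], se_y = oc$se[1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "adjusted_for") <- outcomeCovariates
  out
}

checkSummary <- function(summary) {
  need <- c("beta_x", "se_x", "beta_y", "se_y")
  if (!all(need %in% colnames(summary)))
    stop(sprintf("summary needs columns %s", paste(need, collapse = ", ")))
  if (!nrow(summary)) stop("at least one instrument is required")
  if (any(summary$se_x <= 0 | summary$se_y <= 0))
    stop("standard errors must be positive")
  summary
}

# Per-instrument ratio estimates theta_j = beta_y / beta_x with first-order
# delta-method SE se_y/|beta_x| (second order adds the beta_x variance term).
ratioEstimates <- function(summary, seOrder = c("first", "second")) {
  seOrder <- match.arg(seOrder)
  zero <- summary$beta_x == 0
  if (any(zero)) {
    message(sprintf("instrument(s) rejected (beta_x = 0): %s",
                    paste(summary$snp_id[zero], collapse = ", ")))
    summary <- summary[!zero, , drop = FALSE]
    if (!nrow(summary)) stop("no usable instruments (all beta_x = 0)")
  }
  theta <- summary$beta_y / summary$beta_x
  se <- if (seOrder == "first") summary$se_y / abs(summary$beta_x) else
    sqrt(summary$se_y^2 / summary$beta_x^2 +
           summary$beta_y^2 * summary$se_x^2 / summary$beta_x^4)
  data.frame(snp_id = if (is.null(summary$snp_id)) NA_character_ else
    summary$snp_id, theta = theta, se = se, stringsAsFactors = FALSE)
}

newMREstimate <- function(method, theta, se, nInstruments, diagnostics,
                          ci = theta + c(-1.96, 1.96) * se,
                          orConvention = "0.9") {
  orp <- orPer10PctDecrease(theta, ci = ci, convention = orConvention)
  methods::new("MREstimate", method = method, theta = theta, se = se,
               ci = ci, orPer10 = orp$or, orCI = orp$ci,
               nInstruments = as.integer(nInstruments),
               diagnostics = diagnostics)
}

#' Inverse-variance weighted MR estimate
#'
#' Combines the per-instrument ratio estimates `theta_j = beta_y_j / beta_x_j`
#' with fixed-effect inverse-variance weights `w_j = 1 / se(theta_j)^2`:
#' the estimate is the weighted mean with standard error
#' `(sum w_j)^(-1/2)`. Instruments with `beta_x = 0` are rejected with a
#' message.
#'
#' @param summary data.frame of per-instrument associations (`beta_x`, `se_x`,
#'   `beta_y`, `se_y`), e.g. from [summaryAssociations()] or
#'   [studyInstrumentSummary()].
#' @param seOrder "first" (default; ratio SE `se_y/|beta_x|`) or "second"
#'   (adds the first-stage variance term; of interest with weak instruments).
#' @param orConvention see [orPer10PctDecrease()].
#' @return an [MREstimate].
#' @examples
#' ivwEstimate(studyInstrumentSummary())
#' @export
ivwEstimate <- function(summary, seOrder = "first", orConvention = "0.9") {
  summary <- checkSummary(summary)
  r <- ratioEstimates(summary, seOrder)
  w <- 1 / r$se^2
  theta <- sum(w * r$theta) / sum(w)
  se <- 1 / sqrt(sum(w))
  newMREstimate("ivw", theta, se, nrow(r),
                list(ratio = r, converged = TRUE),
                orConvention = orConvention)
}

# Profile negative log-likelihood machinery for the ML estimator: for fixed
# theta the per-instrument true exposure effects have the closed form
# xi_j = (bx/sx^2 + theta*by/sy^2) / (1/sx^2 + theta^2/sy^2).
mlNegLogLik <- function(par, summary) {
  theta <- par[1L]
  xi <- par[-1L]
  sum((summary$beta_x - xi)^2 / (2 * summary$se_x^2) +
        (summary$beta_y - theta * xi)^2 / (2 * summary$se_y^2))
}

mlProfileXi <- function(theta, summary) {
  (summary$beta_x / summary$se_x^2 + theta * summary$beta_y / summary$se_y^2) /
    (1 / summary$se_x^2 + theta^2 / summary$se_y^2)
}

#' Maximum likelihood MR estimate
#'
#' Jointly models the observed instrument-exposure and instrument-outcome
#' coefficients as independent normals `beta_x_j ~ N(xi_j, se_x_j^2)` and
#' `beta_y_j ~ N(theta xi_j, se_y_j^2)` and maximizes the likelihood over
#' `(xi_1..xi_J, theta)`. The profile over `theta` is optimized numerically
#' (the `xi_j` have a closed form given `theta`); the standard error comes
#' from the observed information of the full likelihood at the optimum. With
#' `se_x -> 0` the estimate converges to the IVW estimate.
#'
#' @inheritParams ivwEstimate
#' @return an [MREstimate]; `diagnostics$converged` reports optimizer status.
#' @examples
#' mlEstimate(studyInstrumentSummary())
#' @export
mlEstimate <- function(summary, orConvention = "0.9") {
  summary <- checkSummary(summary)
  usable <- summary[summary$beta_x != 0 | summary$beta_y != 0, , drop = FALSE]
  if (!nrow(usable)) stop("no usable instruments")
  init <- ivwEstimate(summary)@theta
  r <- tryCatch(ratioEstimates(summary), error = function(e) NULL)
  span <- if (is.null(r)) 10 else diff(range(r$theta)) + 10 * max(r$se)
  lower <- init - max(span, 10)
  upper <- init + max(span, 10)
  prof <- function(theta)
    mlNegLogLik(c(theta, mlProfileXi(theta, usable)), usable)
  opt <- optimize(prof, interval = c(lower, upper), tol = 1e-10)
  theta <- opt$minimum
  converged <- theta > lower + 1e-6 && theta < upper - 1e-6
  if (!converged)
    warning("maximum likelihood estimate at the search boundary")
  par <- c(theta, mlProfileXi(theta, usable))
  H <- optimHess(par, mlNegLogLik, summary = usable)
  se <- tryCatch(sqrt(solve(H)[1L, 1L]), error = function(e) NA_real_)
  newMREstimate("ml", theta, se, nrow(usable),
                list(converged = converged, negloglik = opt$objective),
                orConvention = orConvention)
}

# Weighted normal-kernel density of the ratio estimates; weights sum to 1.
mbeDensity <- function(x, theta, w, h) {
  vapply(x, function(v) sum(w * dnorm((v - theta) / h)) / h, numeric(1L))
}

mbeMode <- function(theta, w, h, nGrid = 2001L) {
  if (diff(range(theta)) == 0) return(theta[1L])
  lo <- min(theta) - 3 * h
  hi <- max(theta) + 3 * h
  grid <- seq(lo, hi, length.out = nGrid)
  dens <- mbeDensity(grid, theta, w, h)
  i <- which.max(dens)
  step <- grid[2L] - grid[1L]
  optimize(function(v) -mbeDensity(v, theta, w, h),
           interval = c(grid[max(1L, i - 1L)], grid[min(nGrid, i + 1L)]),
           tol = step * 1e-4)$minimum
}

# Modified Silverman bandwidth on the ratio estimates (MAD-based scale).
mbeBandwidth <- function(theta, factor = 1) {
  J <- length(theta)
  s <- min(sd(theta), mad(theta))
  if (!is.finite(s) || s == 0) s <- sd(theta)
  if (!is.finite(s) || s == 0) s <- 1e-8
  factor * 0.9 * s * J^(-1 / 5)
}

#' Mode-based MR estimate
#'
#' The causal effect is estimated as the mode of an inverse-variance weighted
#' normal-kernel density of the per-instrument ratio estimates; the mode is
#' robust to a minority of invalid instruments. The bandwidth is a modified
#' (median-absolute-deviation based) Silverman rule scaled by
#' `bandwidthFactor`; the confidence interval comes from a seeded parametric
#' bootstrap (`theta_j* ~ N(theta_j, se_j)`, re-mode, percentile interval).
#'
#' @inheritParams ivwEstimate
#' @param bandwidthFactor multiplier of the Silverman bandwidth (default 1).
#' @param nBoot parametric bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return an [MREstimate]; with fewer than 3 instruments the mode is
#'   statistically degenerate and `diagnostics$degenerate` is TRUE (a warning
#'   is emitted, the estimate is still computed).
#' @examples
#' mbeEstimate(studyInstrumentSummary(), seed = 1)
#' @export
mbeEstimate <- function(summary, bandwidthFactor = 1, nBoot = 1000L,
                        seed = NULL, orConvention = "0.9") {
  summary <- checkSummary(summary)
  r <- ratioEstimates(summary)
  degenerate <- nrow(r) < 3L
  if (degenerate)
    warning("fewer than 3 instruments: mode-based estimate is degenerate")
  w <- (1 / r$se^2) / sum(1 / r$se^2)
  zeroSpread <- diff(range(r$theta)) == 0
  h <- mbeBandwidth(r$theta, bandwidthFactor)
  theta <- mbeMode(r$theta, w, h)
  if (!is.null(seed)) set.seed(as.integer(seed))
  boot <- vapply(seq_len(nBoot), function(b) {
    tb <- rnorm(nrow(r), r$theta, r$se)
    mbeMode(tb, w, mbeBandwidth(tb, bandwidthFactor))
  }, numeric(1L))
  se <- mad(boot)
  ci <- unname(quantile(boot, c(0.025, 0.975), type = 7))
  newMREstimate("mbe", theta, se, nrow(r),
                list(converged = TRUE, nBoot = nBoot, bandwidth = h,
                     degenerate = degenerate, zeroSpread = zeroSpread,
                     ratio = r),
                ci = ci, orConvention = orConvention)
}

#' Odds ratio per 10 percent exposure decrease
#'
#' Rescales a causal log-odds ratio per unit ln-exposure to the odds ratio per
#' 10 percent decrease of the untransformed exposure. A 10 percent decrease
#' multiplies the exposure by 0.9, i.e. shifts the ln exposure by `ln 0.9`, so
#' `OR = exp(theta * ln 0.9)` (default). The alternative convention `"10/9"`
#' reads "per 10 percent decrease" as the change undone by a 10/9-fold
#' increase, `OR = exp(theta * ln(10/9))` — the reciprocal of the default.
#' Interval endpoints are swapped where needed so `low < high`.
#'
#' @param theta causal log-odds per unit ln exposure.
#' @param se optional standard error (used if `ci` missing).
#' @param ci optional length-2 interval for `theta`.
#' @param convention "0.9" or "10/9".
#' @return list with `or` and `ci`.
#' @examples
#' orPer10PctDecrease(-2.576)$or # about 1.312
#' @export
orPer10PctDecrease <- function(theta, se = NULL, ci = NULL,
                               convention = c("0.9", "10/9")) {
  convention <- match.arg(convention)
  if (!is.finite(theta)) stop("theta must be finite")
  k <- if (convention == "0.9") log(0.9) else log(10 / 9)
  if (is.null(ci)) {
    ci <- if (is.null(se)) c(NA_real_, NA_real_) else
      theta + c(-1.96, 1.96) * se
  }
  list(or = exp(theta * k), ci = sort(exp(ci * k)))
}

#' @rdname MREstimate-class
#' @param object an `MREstimate`.
#' @export
setMethod("show", "MREstimate", function(object) {
  label <- c(ivw = "Inverse-variance weighted", ml = "Maximum likelihood",
             mbe = "Mode-based")[object@method]
  cat(sprintf("%s MR estimate (%d instruments)\n", label,
              object@nInstruments))
  cat(sprintf("  theta (log-odds per unit ln exposure): %.4f (SE %.4f), 95%% CI (%.4f, %.4f)\n",
              object@theta, object@se, object@ci[1L], object@ci[2L]))
  cat(sprintf("  OR per 10%% exposure decrease: %.3f (%.3f, %.3f)\n",
              object@orPer10, object@orCI[1L], object@orCI[2L]))
})

#' Accessors for MREstimate
#'
#' @param x an [MREstimate].
#' @return `mrTheta`/`mrSE`: the causal log-odds estimate per unit ln exposure
#'   and its SE; `mrCI`: its 95 percent interval; `mrOR`: list with the odds
#'   ratio per 10 percent exposure decrease and its interval.
#' @export
mrTheta <- function(x) { stopifnot(is(x, "MREstimate")); x@theta }

#' @rdname mrTheta
#' @export
mrSE <- function(x) { stopifnot(is(x, "MREstimate")); x@se }

#' @rdname mrTheta
#' @export
mrCI <- function(x) { stopifnot(is(x, "MREstimate")); x@ci }

#' @rdname mrTheta
#' @export
mrOR <- function(x) {
  stopifnot(is(x, "MREstimate"))
  list(or = x@orPer10, ci = x@orCI)
}

#' Two-stage least squares diagnostic on the genetic risk score
#'
#' Cross-check of the summary-statistic estimators: regress exposure on the
#' GRS (first stage), then case status on the fitted exposure by logistic
#' regression (second stage, covariate-adjusted). With strong instruments and
#' a linear causal mechanism the coefficient approximates the causal theta.
#'
#' @param cohort an [MRCohort].
#' @param grs per-subject genetic risk score ([buildGRS()]).
#' @param covariates covariates adjusted for in the second stage.
#' @return data.frame with `theta`, `se`, `first_stage_f` (first-stage F
#'   statistic) and `n_used`.
#' @export
tslsDiagnostic <- function(cohort, grs, covariates = character()) {
  x <- exposureValues(cohort)
  keep <- !is.na(x) & !is.na(grs)
  first <- lm(x[keep] ~ grs[keep])
  fstat <- unname(summary(first)$fstatistic[1L])
  xhat <- rep(NA_real_, length(x))
  xhat[keep] <- fitted(first)
  out <- assocFit(caseStatus(cohort), cbind(xhat = xhat),
                  covariateData(cohort)[, covariates, drop = FALSE],
                  family = binomial(), minN = 20L)
  data.frame(theta = out$effect, se = out$se, first_stage_f = fstat,
             n_used = out$n_used)
}
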