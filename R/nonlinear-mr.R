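#' Instrument-free exposure residuals
#'
#' Removes the genetic contribution from the exposure by regressing the
#' ln-scale exposure on the genetic risk score and returning the residuals.
#' Stratifying on these residuals (rather than on the raw exposure) avoids the
#' collider bias that stratifying on a variable downstream of the instrument
#' would introduce.
#'
#' @param cohort an [MRCohort].
#' @param grs per-subject genetic risk score ([buildGRS()]).
#' @param fitOn "all" (default) fits the exposure-GRS regression on all
#'   subjects; "controls" fits on controls and applies the fit to everyone.
#' @return numeric residual vector (NA where exposure or GRS is missing), with
#'   attributes `slope` and `intercept` of the fitted first stage. Residuals
#'   are mean-zero and uncorrelated with the GRS in the fitting set.
#' @export
ivFreeExposure <- function(cohort, grs, fitOn = c("all", "controls")) {
  fitOn <- match.arg(fitOn)
  x <- exposureValues(cohort)
  if (length(grs) != length(x)) stop("grs length must match the cohort")
  if (length(unique(grs[!is.na(grs)])) < 2L) stop("constant GRS")
  inFit <- if (fitOn == "controls") caseStatus(cohort) == 0L else
    rep(TRUE, length(x))
  use <- inFit & !is.na(x) & !is.na(grs)
  fit <- lm(x[use] ~ grs[use])
  a <- coef(fit)[[1L]]
  b <- coef(fit)[[2L]]
  res <- x - (a + b * grs)
  attr(res, "slope") <- b
  attr(res, "intercept") <- a
  res
}

#' Quantile stratification
#'
#' Cuts a vector into K groups of (nearly) equal size by rank, ties broken by
#' stable input order, so group sizes differ by at most one.
#'
#' @param values numeric vector (typically IV-free exposure residuals).
#' @param K number of strata (2-10 is sensible; K = 1 is allowed so that the
#'   unstratified analysis is a special case).
#' @return integer stratum index 1..K per element (`NA` where `values` is
#'   `NA`).
#' @export
stratifyResiduals <- function(values, K) {
  K <- as.integer(K)
  if (K < 1L) stop("K must be at least 1")
  ok <- !is.na(values)
  n <- sum(ok)
  if (length(unique(values[ok])) < K)
    stop("K exceeds the number of distinct values")
  r <- rank(values[ok], ties.method = "first")
  idx <- rep(NA_integer_, length(values))
  idx[ok] <- as.integer(floor((r - 1) * K / n) + 1L)
  idx
}

#' Per-stratum localized average causal effect (LACE) estimates
#'
#' Within each stratum, estimates the GRS-exposure coefficient (`beta_x`,
#' linear regression, unadjusted) and the GRS-outcome coefficient (`beta_y`,
#' logistic regression, covariate-adjusted); the LACE is the ratio
#' `beta_y / beta_x` with a first-order delta-method standard error
#' `se_y / |beta_x|` (option "second" adds the first-stage variance term).
#' Strata lacking both outcome classes or with constant GRS are flagged
#' (`ok = FALSE`) and excluded from the non-linearity tests.
#'
#' @param cohort an [MRCohort].
#' @param grs genetic risk score per subject.
#' @param strata integer stratum assignment from [stratifyResiduals()].
#' @param covariates covariates adjusted for in the outcome stage.
#' @param seOrder "first" or "second" (see [ivwEstimate()]).
#' @return data.frame with one row per stratum: `k`, `n`, `x_mean`, `x_low`,
#'   `x_high` (exposure summaries), `beta_x`, `se_x`, `beta_y`, `se_y`,
#'   `lace`, `se_lace`, `ok`.
#' @export
laceEstimates <- function(cohort, grs, strata, covariates = character(),
                          seOrder = c("first", "second")) {
  seOrder <- match.arg(seOrder)
  x <- exposureValues(cohort)
  y <- caseStatus(cohort)
  cv <- covariateData(cohort)[, covariates, drop = FALSE]
  ks <- sort(unique(strata[!is.na(strata)]))
  rows <- lapply(ks, function(k) {
    i <- which(!is.na(strata) & strata == k)
    out <- data.frame(k = k, n = length(i),
                      x_mean = mean(x[i], na.rm = TRUE),
                      x_low = min(x[i], na.rm = TRUE),
                      x_high = max(x[i], na.rm = TRUE),
                      beta_x = NA_real_, se_x = NA_real_,
                      beta_y = NA_real_, se_y = NA_real_,
                      lace = NA_real_, se_lace = NA_real_, ok = FALSE)
    bad <- length(unique(grs[i][!is.na(grs[i])])) < 2L ||
      length(unique(y[i])) < 2L
    if (bad) {
      warning(sprintf("stratum %d flagged (constant GRS or single outcome class)", k))
      return(out)
    }
    fx <- tryCatch(assocFit(x[i], cbind(grs = grs[i]), NULL, minN = 3L),
                   error = function(e) NULL)
    fy <- tryCatch(assocFit(y[i], cbind(grs = grs[i]),
                            cv[i, , drop = FALSE], family = binomial(),
                            minN = 3L),
                   error = function(e) NULL)
    if (is.null(fx) || is.null(fy) || fx$effect == 0) {
      warning(sprintf("stratum %d flagged (unestimable stage)", k))
      return(out)
    }
    out$beta_x <- fx$effect; out$se_x <- fx$se
    out$beta_y <- fy$effect; out$se_y <- fy$se
    out$lace <- fy$effect / fx$effect
    out$se_lace <- if (seOrder == "first") fy$se / abs(fx$effect) else
      sqrt(fy$se^2 / fx$effect^2 + fy$effect^2 * fx$se^2 / fx$effect^4)
    out$ok <- TRUE
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

okStrata <- function(strataResults, minK) {
  s <- strataResults[strataResults$ok & is.finite(strataResults$lace) &
                       is.finite(strataResults$se_lace) &
                       strataResults$se_lace > 0, , drop = FALSE]
  if (nrow(s) < minK)
    stop(sprintf("at least %d usable strata are required", minK))
  s[order(s$x_mean), , drop = FALSE]
}

#' Quadratic test for non-linearity
#'
#' Tests for a linear trend of the LACE estimates across strata: weighted
#' least squares (meta-regression with weights `se_lace^-2`) of `lace` on the
#' stratum mean exposure; the p-value is the two-sided normal test of the
#' slope against zero, with the slope variance taken from the weighted
#' information matrix (stratum variances treated as known).
#'
#' @param strataResults output of [laceEstimates()].
#' @return list with `slope`, `se`, `p.value`.
#' @export
quadraticTest <- function(strataResults) {
  s <- okStrata(strataResults, 3L)
  w <- 1 / s$se_lace^2
  X <- cbind(1, s$x_mean)
  XtWX <- crossprod(X, w * X)
  V <- solve(XtWX)
  beta <- V %*% crossprod(X, w * s$lace)
  slope <- beta[2L, 1L]
  se <- sqrt(V[2L, 2L])
  list(slope = slope, se = se,
       p.value = 2 * pnorm(-abs(slope / se)))
}

#' Cochran's Q test for heterogeneity of LACE estimates
#'
#' Assesses whether the stratum LACE estimates differ more than expected by
#' chance: `Q = sum w_k (lace_k - theta_bar)^2` with `w_k = se_lace_k^-2` and
#' `theta_bar` the weighted mean; under homogeneity Q is chi-squared with
#' K - 1 degrees of freedom.
#'
#' @param strataResults output of [laceEstimates()].
#' @return list with `Q`, `df`, `p.value`.
#' @export
cochranQTest <- function(strataResults) {
  s <- okStrata(strataResults, 2L)
  w <- 1 / s$se_lace^2
  tbar <- sum(w * s$lace) / sum(w)
  Q <- sum(w * (s$lace - tbar)^2)
  df <- nrow(s) - 1L
  list(Q = Q, df = df, p.value = pchisq(Q, df, lower.tail = FALSE))
}

#' Conventional fractional-polynomial powers of degree 1
#' @return `c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)`.
#' @export
fracpolyPowers <- function() c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

# Derivative basis of the degree-1 fractional polynomial with power p:
# the causal curve is c * G_p(x), so the LACE (a local derivative) follows
# c * g_p(x) with g_p(x) = x^(p-1); power 0 is the logarithmic curve, whose
# derivative 1/x is x^(0-1), so the same expression covers it.
fracpolyBasis <- function(x, power) x^(power - 1)

fracpolyFitOne <- function(s, power, w) {
  g <- fracpolyBasis(s$x_mean, power)
  c_hat <- sum(w * g * s$lace) / sum(w * g^2)
  rssw <- sum(w * (s$lace - c_hat * g)^2)
  list(power = power, coef = c_hat, se_coef = 1 / sqrt(sum(w * g^2)),
       rssw = rssw)
}

#' Fractional polynomial test for non-linearity
#'
#' Fits, for each power in the conventional set, the one-parameter derivative
#' model `lace_k = c * x_mean_k^(power - 1)` by weighted Gaussian likelihood
#' and compares the best-fitting power against the linear model (power 1,
#' constant LACE) by a 1-df chi-squared likelihood-ratio test. Power selection
#' multiplicity is ignored, as in the reference semiparametric method, which
#' makes the test mildly anti-conservative. Stratum means must be positive;
#' otherwise a positivity shift `1 - min(x_mean)` is applied and recorded.
#'
#' @param strataResults output of [laceEstimates()].
#' @param powers candidate powers (default [fracpolyPowers()]; must contain 1).
#' @return list with `best_power`, `statistic`, `p.value`, `coef` (scale of
#'   the best fit), `shift`, and `fits` (per-power coefficient and weighted
#'   RSS).
#' @export
fracpolyTest <- function(strataResults, powers = fracpolyPowers()) {
  if (!1 %in% powers) stop("the power set must contain 1 (the linear model)")
  s <- okStrata(strataResults, 3L)
  shift <- if (min(s$x_mean) <= 0) 1 - min(s$x_mean) else 0
  s$x_mean <- s$x_mean + shift
  w <- 1 / s$se_lace^2
  fits <- lapply(powers, function(p) fracpolyFitOne(s, p, w))
  rss <- vapply(fits, `[[`, numeric(1L), "rssw")
  best <- which.min(rss)
  linear <- which(powers == 1)
  stat <- max(0, rss[linear] - rss[best])
  list(best_power = powers[best], statistic = stat,
       p.value = pchisq(stat, df = 1, lower.tail = FALSE),
       coef = fits[[best]]$coef, shift = shift,
       fits = data.frame(power = powers, coef = vapply(fits, `[[`,
                           numeric(1L), "coef"), rssw = rss))
}

# Contiguous stratum boundaries: midpoints between consecutive stratum mean
# exposures, with the observed exposure extremes as outer edges. Residual
# strata overlap in raw exposure, so midpoints of means give a monotone
# partition to integrate over.
strataBoundaries <- function(s) {
  K <- nrow(s)
  inner <- if (K > 1L) (s$x_mean[-K] + s$x_mean[-1L]) / 2 else numeric(0)
  c(min(s$x_low), inner, max(s$x_high))
}

#' Piecewise-linear causal curve
#'
#' Reconstructs the causal effect curve `h(x)` (log-odds difference relative
#' to the reference exposure) by integrating the constant stratum slope
#' `lace_k` across contiguous exposure segments; the curve is continuous at
#' the segment boundaries by construction. Pointwise variance accumulates the
#' squared segment lengths times the LACE variances (independent strata).
#'
#' @param strataResults output of [laceEstimates()].
#' @param reference exposure value at which `h = 0`; default the
#'   stratum-size-weighted mean exposure. Must lie in the observed range.
#' @param n number of grid points.
#' @return data.frame with `x`, `effect`, `ci_low`, `ci_high`, `method`.
#' @export
piecewiseCurve <- function(strataResults, reference = NULL, n = 101L) {
  s <- okStrata(strataResults, 1L)
  b <- strataBoundaries(s)
  if (is.null(reference)) reference <- sum(s$n * s$x_mean) / sum(s$n)
  if (reference < b[1L] || reference > b[length(b)])
    stop("reference outside the observed exposure range")
  hOf <- function(x) {
    sgn <- sign(x - reference)
    lo <- pmin(x, reference); hi <- pmax(x, reference)
    eff <- vr <- 0
    for (k in seq_len(nrow(s))) {
      L <- max(0, min(hi, b[k + 1L]) - max(lo, b[k]))
      eff <- eff + L * s$lace[k]
      vr <- vr + L^2 * s$se_lace[k]^2
    }
    c(effect = sgn * eff, se = sqrt(vr))
  }
  grid <- seq(b[1L], b[length(b)], length.out = n)
  vals <- t(vapply(grid, hOf, c(effect = 0, se = 0)))
  data.frame(x = grid, effect = vals[, "effect"],
             ci_low = vals[, "effect"] - 1.96 * vals[, "se"],
             ci_high = vals[, "effect"] + 1.96 * vals[, "se"],
             method = "piecewise", stringsAsFactors = FALSE)
}

# Antiderivative of the fractional-polynomial derivative basis.
fracpolyAntiderivative <- function(x, power)
  if (power == 0) log(x) else x^power / power

#' Fractional-polynomial causal curve
#'
#' The degree-1 fractional-polynomial causal curve
#' `h(x) = c * (G_p(x) - G_p(reference))`, where `G_p` is the antiderivative
#' of the derivative basis `x^(p-1)` (i.e. `x^p / p`, or `log(x)` for power
#' 0) and `c` the weighted fit from [fracpolyTest()]. The pointwise interval
#' is the delta-method interval on `c`.
#'
#' @param strataResults output of [laceEstimates()].
#' @param power the fractional-polynomial power; default the best power from
#'   [fracpolyTest()].
#' @param reference exposure value at which `h = 0` (default as in
#'   [piecewiseCurve()]).
#' @param n number of grid points.
#' @return data.frame with `x`, `effect`, `ci_low`, `ci_high`, `method`.
#' @export
fracpolyCurve <- function(strataResults, power = NULL, reference = NULL,
                          n = 101L) {
  s <- okStrata(strataResults, 1L)
  ft <- fracpolyTest(strataResults)
  if (is.null(power)) power <- ft$best_power
  shift <- ft$shift
  w <- 1 / s$se_lace^2
  sShift <- s; sShift$x_mean <- s$x_mean + shift
  fit <- fracpolyFitOne(sShift, power, w)
  b <- strataBoundaries(s)
  if (is.null(reference)) reference <- sum(s$n * s$x_mean) / sum(s$n)
  if (reference < b[1L] || reference > b[length(b)])
    stop("reference outside the observed exposure range")
  grid <- seq(b[1L], b[length(b)], length.out = n)
  dG <- fracpolyAntiderivative(grid + shift, power) -
    fracpolyAntiderivative(reference + shift, power)
  data.frame(x = grid, effect = fit$coef * dG,
             ci_low = fit$coef * dG - 1.96 * abs(dG) * fit$se_coef,
             ci_high = fit$coef * dG + 1.96 * abs(dG) * fit$se_coef,
             method = "fracpoly", stringsAsFactors = FALSE)
}

#' Semiparametric non-linear MR analysis
#'
#' End-to-end non-linear stage: IV-free residuals, quantile stratification
#' into K strata, per-stratum LACE estimation, the three non-linearity tests
#' (quadratic trend, Cochran's Q, fractional polynomial), and the
#' piecewise-linear and fractional-polynomial causal curves.
#'
#' @inheritParams laceEstimates
#' @param K number of strata (default 5, displayed as exposure quintiles).
#' @param fitOn fitting set for the IV-free residual regression.
#' @param reference reference exposure for the curves (default: weighted mean).
#' @param powers fractional-polynomial power set.
#' @return a [NonlinearMR] object.
#' @export
nonlinearMR <- function(cohort, grs, K = 5L, covariates = character(),
                        fitOn = "all", reference = NULL,
                        powers = fracpolyPowers(),
                        seOrder = "first") {
  res <- ivFreeExposure(cohort, grs, fitOn = fitOn)
  strata <- stratifyResiduals(res, K)
  lace <- laceEstimates(cohort, grs, strata, covariates, seOrder = seOrder)
  qt <- quadraticTest(lace)
  cq <- cochranQTest(lace)
  fp <- fracpolyTest(lace, powers)
  tests <- data.frame(
    test = c("quadratic", "cochran_q", "fracpoly"),
    statistic = c(qt$slope / qt$se, cq$Q, fp$statistic),
    df = c(NA_integer_, cq$df, 1L),
    p_value = c(qt$p.value, cq$p.value, fp$p.value),
    stringsAsFactors = FALSE
  )
  curves <- list(piecewise = piecewiseCurve(lace, reference),
                 fracpoly = fracpolyCurve(lace, fp$best_power, reference))
  methods::new("NonlinearMR", strata = lace, tests = tests, curves = curves,
               K = as.integer(K), bestPower = fp$best_power,
               shift = fp$shift)
}

#' Accessors for NonlinearMR
#' @param x a [NonlinearMR].
#' @return `laceTable`: per-stratum data.frame; `nonlinearityTests`: test
#'   table; `causalCurves`: list of curve data.frames.
#' @name NonlinearMR-accessors
NULL

#' @rdname NonlinearMR-accessors
#' @export
setMethod("laceTable", "NonlinearMR", function(x) x@strata)

#' @rdname NonlinearMR-accessors
#' @export
setMethod("nonlinearityTests", "NonlinearMR", function(x) x@tests)

#' @rdname NonlinearMR-accessors
#' @export
setMethod("causalCurves", "NonlinearMR", function(x) x@curves)

#' @rdname NonlinearMR-class
#' @param object a `NonlinearMR`.
#' @export
setMethod("show", "NonlinearMR", function(object) {
  cat(sprintf("Non-linear MR: %d strata, best fractional-polynomial power %g\n",
              object@K, object@bestPower))
  t <- object@tests
  for (i in seq_len(nrow(t)))
    cat(sprintf("  %-10s p = %.4g\n", t$test[i], t$p_value[i]))
})
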