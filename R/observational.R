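# Deterministic Shapiro-Wilk normality check; the test is defined for
# 3..5000 observations, so larger groups are thinned to an evenly spaced
# subsample of the sorted values (deterministic, seed-free).
isNormal <- function(v, alpha = 0.05) {
  v <- v[!is.na(v)]
  if (length(v) < 3L) return(FALSE)
  if (length(v) > 5000L)
    v <- sort(v)[round(seq(1L, length(v), length.out = 5000L))]
  if (diff(range(v)) == 0) return(FALSE)
  shapiro.test(v)$p.value >= alpha
}

fmtMeanSD <- function(v)
  sprintf("%.2f ± %.2f", mean(v, na.rm = TRUE), sd(v, na.rm = TRUE))

fmtMedianIQR <- function(v) {
  q <- quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7)
  sprintf("%.2f (%.2f, %.2f)", q[2L], q[1L], q[3L])
}

#' Case-control descriptive table with group tests
#'
#' Summarizes each variable by case status and tests the between-group
#' difference: continuous variables are shown as mean +/- SD and compared by
#' the t test when Shapiro-Wilk does not reject normality (at alpha 0.05) in
#' both groups, otherwise as median (interquartile range, linear-interpolation
#' quartiles) with the Mann-Whitney U test (normal approximation with tie
#' correction); categorical variables as n (percent) per level with the
#' chi-squared test.
#'
#' @param cohort an [MRCohort].
#' @param variables variable names among `exposure` and the cohort covariates
#'   (default: exposure plus all covariates).
#' @param types optional named character vector overriding the inferred type
#'   ("continuous" or "categorical"; variables with at most 3 distinct values
#'   are inferred categorical).
#' @return data.frame with columns `variable`, `level`, `summary_controls`,
#'   `summary_cases`, `test_used`, `p_value` (levels of a categorical variable
#'   share the test row).
#' @export
describeAndTest <- function(cohort, variables = NULL, types = NULL) {
  y <- caseStatus(cohort)
  dat <- cbind(exposure = exposureValues(cohort), covariateData(cohort))
  if (is.null(variables)) variables <- colnames(dat)
  rows <- list()
  for (v in variables) {
    vals <- dat[[v]]
    if (is.null(vals)) stop(sprintf("unknown variable '%s'", v))
    if (all(is.na(vals))) {
      warning(sprintf("variable '%s' is all-missing: skipped", v))
      next
    }
    type <- if (!is.null(types) && v %in% names(types)) types[[v]] else
      if (is.character(vals) || is.factor(vals) ||
          length(unique(vals[!is.na(vals)])) <= 3L) "categorical" else
        "continuous"
    a <- vals[y == 0L]; b <- vals[y == 1L]
    if (type == "continuous") {
      normal <- isNormal(a) && isNormal(b)
      if (normal) {
        p <- t.test(b, a)$p.value
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = NA_character_,
          summary_controls = fmtMeanSD(a), summary_cases = fmtMeanSD(b),
          test_used = "t", p_value = p, stringsAsFactors = FALSE)
      } else {
        p <- suppressWarnings(
          wilcox.test(b, a, exact = FALSE, correct = FALSE)$p.value)
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = NA_character_,
          summary_controls = fmtMedianIQR(a), summary_cases = fmtMedianIQR(b),
          test_used = "mann-whitney", p_value = p, stringsAsFactors = FALSE)
      }
    } else {
      tab <- table(factor(vals), factor(y, levels = c(0L, 1L)))
      p <- if (nrow(tab) < 2L) NA_real_ else
        suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
      for (lv in rownames(tab)) {
        nc <- tab[lv, "0"]; ncs <- tab[lv, "1"]
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = lv,
          summary_controls = sprintf("%d (%.1f%%)", nc,
                                     100 * nc / sum(tab[, "0"])),
          summary_cases = sprintf("%d (%.1f%%)", ncs,
                                  100 * ncs / sum(tab[, "1"])),
          test_used = "chi-squared", p_value = p, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Covariate-adjusted observational exposure-outcome regression
#'
#' Conventional (non-genetic) case-control association: logistic regression of
#' case status on the ln-scale exposure plus covariates, reported as the odds
#' ratio per unit ln exposure with a Wald interval.
#'
#' @param cohort an [MRCohort].
#' @param covariates covariate names to adjust for.
#' @return data.frame with `or`, `ci_low`, `ci_high`, `log_or`, `se`,
#'   `p_value`, `n_used`, `adjusted_for`.
#' @export
adjustedExposureRegression <- function(cohort, covariates = character()) {
  cv <- covariateData(cohort)[, covariates, drop = FALSE]
  x <- exposureValues(cohort)
  df <- data.frame(.y = caseStatus(cohort), .x = x)
  if (ncol(cv)) df <- cbind(df, cv)
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) < 20L) stop("fewer than 20 complete cases")
  fml <- as.formula(paste(".y ~", paste(
    sprintf("`%s`", setdiff(colnames(df), ".y")), collapse = " + ")))
  fit <- suppressWarnings(glm(fml, data = df, family = binomial()))
  if (any(is.na(coef(fit))))
    stop(sprintf("rank-deficient design (aliased: %s)",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  if (!fit$converged || any(abs(coef(fit)[-1L]) > 15))
    warning("possible separation or non-convergence")
  sm <- summary(fit)$coefficients
  est <- sm[".x", 1L]; se <- sm[".x", 2L]
  data.frame(or = exp(est), ci_low = exp(est - 1.96 * se),
             ci_high = exp(est + 1.96 * se), log_or = est, se = se,
             p_value = sm[".x", 4L], n_used = nrow(df),
             adjusted_for = paste(covariates, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Exposure-quintile case/control comparison
#'
#' Cuts the raw exposure into K pooled quantile groups (cases and controls
#' together) and, within each group, compares case and control exposures by
#' the Mann-Whitney U test, emitting box-plot-ready summaries (median,
#' quartiles, whiskers at 1.5 interquartile ranges).
#'
#' @param cohort an [MRCohort].
#' @param K number of quantile groups (default 5, quintiles).
#' @return data.frame with one row per (quantile group, case status): columns
#'   `quintile`, `group` ("controls"/"cases"), `n`, `median`, `q1`, `q3`,
#'   `whisker_low`, `whisker_high`, `p_value` (shared within group pair; `NA`
#'   with `flagged = TRUE` when a cell is empty).
#' @export
quintileComparison <- function(cohort, K = 5L) {
  x <- exposureValues(cohort)
  y <- caseStatus(cohort)
  if (sum(!is.na(x)) < 50L) stop("at least 50 non-missing exposures required")
  q <- stratifyResiduals(x, K)
  rows <- list()
  for (k in sort(unique(q[!is.na(q)]))) {
    xa <- x[!is.na(q) & q == k & y == 0L]
    xb <- x[!is.na(q) & q == k & y == 1L]
    flagged <- length(xa) == 0L || length(xb) == 0L
    if (flagged) warning(sprintf("quantile group %d has an empty cell", k))
    p <- if (flagged) NA_real_ else suppressWarnings(
      wilcox.test(xb, xa, exact = FALSE, correct = FALSE)$p.value)
    for (grp in c("controls", "cases")) {
      v <- if (grp == "controls") xa else xb
      if (!length(v)) {
        rows[[length(rows) + 1L]] <- data.frame(
          quintile = k, group = grp, n = 0L, median = NA_real_,
          q1 = NA_real_, q3 = NA_real_, whisker_low = NA_real_,
          whisker_high = NA_real_, p_value = p, flagged = flagged,
          stringsAsFactors = FALSE)
        next
      }
      qq <- quantile(v, c(0.25, 0.5, 0.75), type = 7)
      iqr <- qq[3L] - qq[1L]
      rows[[length(rows) + 1L]] <- data.frame(
        quintile = k, group = grp, n = length(v), median = qq[2L],
        q1 = qq[1L], q3 = qq[3L],
        whisker_low = min(v[v >= qq[1L] - 1.5 * iqr]),
        whisker_high = max(v[v <= qq[3L] + 1.5 * iqr]),
        p_value = p, flagged = flagged, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
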