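# Shared regression backend for the association operations. `code` is the
# encoded genotype (vector, or two-column matrix for the co-dominant model).
assocFit <- function(response, code, covars, family = NULL, minN = 10L) {
  code <- as.matrix(code)
  if (is.null(colnames(code)))
    colnames(code) <- if (ncol(code) == 1L) "code" else
      paste0("code", seq_len(ncol(code)))
  df <- data.frame(.y = response, code, check.names = FALSE)
  adjusted <- character(0)
  if (!is.null(covars) && ncol(covars)) {
    adjusted <- colnames(covars)
    df <- cbind(df, covars)
  }
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) < minN)
    stop(sprintf("fewer than %d complete cases", minN))
  for (v in colnames(code))
    if (length(unique(df[[v]])) < 2L)
      stop("encoded genotype is constant: singular design")
  if (length(unique(df$.y)) == 1L) {
    # a constant response fits exactly: zero effect, no evidence either way
    return(data.frame(term = colnames(code), effect = 0, se = 0,
                      ci_low = 0, ci_high = 0, p_value = 1,
                      n_used = nrow(df),
                      adjusted_for = paste(adjusted, collapse = ","),
                      separation = FALSE, stringsAsFactors = FALSE))
  }
  rhs <- paste(sprintf("`%s`", setdiff(colnames(df), ".y")), collapse = " + ")
  fml <- as.formula(paste(".y ~", rhs))
  fit <- if (is.null(family)) lm(fml, data = df) else
    suppressWarnings(glm(fml, data = df, family = family))
  separation <- !is.null(family) &&
    (!fit$converged || any(abs(coef(fit)[-1L]) > 15, na.rm = TRUE))
  sm <- summary(fit)$coefficients
  terms <- sprintf("`%s`", colnames(code))
  terms <- ifelse(terms %in% rownames(sm), terms, colnames(code))
  est <- sm[terms, 1L]
  se <- sm[terms, 2L]
  p <- sm[terms, 4L]
  # a constant response fits exactly: no evidence against the null
  p[is.nan(p) & abs(est) < 1e-12] <- 1
  data.frame(
    term = colnames(code), effect = unname(est), se = unname(se),
    ci_low = unname(est - 1.96 * se), ci_high = unname(est + 1.96 * se),
    p_value = unname(p), n_used = nrow(df),
    adjusted_for = paste(adjusted, collapse = ","),
    separation = separation,
    stringsAsFactors = FALSE
  )
}

encodedSNP <- function(cohort, snp, model, effectAllele) {
  g <- genotypeMatrix(cohort)
  if (!snp %in% colnames(g))
    stop(sprintf("SNP '%s' not present in the cohort", snp))
  encodeGenotype(g[, snp], model = model, effectAllele = effectAllele)
}

#' Instrument-exposure association
#'
#' Least-squares regression of the ln-scale exposure on the encoded genotype,
#' by default restricted to controls (associations of instruments with the
#' exposure are estimated in disease-free subjects to avoid reverse
#' causation) and unadjusted. The genotype coefficient is the mean difference
#' (MD) in ln exposure for the coded contrast.
#'
#' @param cohort an [MRCohort].
#' @param snp SNP id.
#' @param model genetic model ([geneticModels()]); default over-dominant.
#' @param covariates covariate names to adjust for (none by default).
#' @param controls if TRUE (default) restrict to controls.
#' @param effectAllele "alt" or "ref".
#' @return data.frame with one row per genotype contrast: `snp_id`, `term`,
#'   `effect` (MD, ln-exposure units), `se`, `ci_low`, `ci_high` (1.96-normal
#'   interval), `p_value`, `n_used`, `model`, `adjusted_for`.
#' @export
exposureAssociation <- function(cohort, snp, model = "overdominant",
                                covariates = character(),
                                controls = TRUE,
                                effectAllele = "alt") {
  sub <- if (controls) controlsOnly(cohort) else cohort
  code <- encodedSNP(sub, snp, model, effectAllele)
  out <- assocFit(exposureValues(sub), code,
                  covariateData(sub)[, covariates, drop = FALSE])
  cbind(snp_id = snp, out, model = model, stringsAsFactors = FALSE)
}

#' Percentage difference in exposure implied by a ln-scale coefficient
#'
#' @param beta regression coefficient on the natural-log scale.
#' @return `(exp(beta) - 1) * 100`, the percent change in the untransformed
#'   exposure associated with the coded contrast.
#' @examples
#' percentDifference(-0.108) # about -10.24
#' @export
percentDifference <- function(beta) {
  if (any(!is.finite(beta))) stop("beta must be finite")
  (exp(beta) - 1) * 100
}

#' Pleiotropy screen of an instrument against covariates
#'
#' Tests, among controls, whether the encoded genotype is associated with each
#' covariate: mean differences from linear regression for continuous
#' covariates, and for binary covariates both the mean difference on the 0/1
#' coding (the forest-plot-compatible default) and the log-odds from logistic
#' regression.
#'
#' @inheritParams exposureAssociation
#' @param covariates covariate names to screen; default all cohort covariates.
#' @return data.frame with columns `snp_id`, `covariate`, `estimand` ("md" or
#'   "logodds"), `effect`, `se`, `ci_low`, `ci_high`, `p_value`, `n_used`,
#'   `skipped` (TRUE for constant covariates, effect `NA`).
#' @export
pleiotropyScreen <- function(cohort, snp, model = "overdominant",
                             covariates = NULL, effectAllele = "alt") {
  ctrl <- controlsOnly(cohort)
  cv <- covariateData(ctrl)
  if (is.null(covariates)) covariates <- colnames(cv)
  if (!length(covariates)) stop("no covariates to screen")
  code <- encodedSNP(ctrl, snp, model, effectAllele)
  rows <- list()
  emptyRow <- function(covariate, estimand) data.frame(
    snp_id = snp, covariate = covariate, estimand = estimand,
    effect = NA_real_, se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    p_value = NA_real_, n_used = 0L, skipped = TRUE, stringsAsFactors = FALSE)
  for (v in covariates) {
    vals <- cv[[v]]
    if (is.null(vals)) stop(sprintf("unknown covariate '%s'", v))
    if (length(unique(vals[!is.na(vals)])) < 2L) {
      warning(sprintf("covariate '%s' is constant: skipped", v))
      rows[[length(rows) + 1L]] <- emptyRow(v, "md")
      next
    }
    isBinary <- all(vals %in% c(0, 1, NA))
    md <- assocFit(vals, code, NULL)
    rows[[length(rows) + 1L]] <- data.frame(
      snp_id = snp, covariate = v, estimand = "md",
      md[, c("effect", "se", "ci_low", "ci_high", "p_value", "n_used")],
      skipped = FALSE, stringsAsFactors = FALSE)
    if (isBinary) {
      lo <- assocFit(vals, code, NULL, family = binomial())
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = snp, covariate = v, estimand = "logodds",
        lo[, c("effect", "se", "ci_low", "ci_high", "p_value", "n_used")],
        skipped = FALSE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default instrument-selection thresholds
#'
#' @return named list: `maf_min` 0.05, `hwe_alpha` 0.05, `exposure_alpha`
#'   0.05, `screen_alpha` 0.05 (two-sided, uncorrected throughout).
#' @export
defaultThresholds <- function()
  list(maf_min = 0.05, hwe_alpha = 0.05, exposure_alpha = 0.05,
       screen_alpha = 0.05)

#' Apply the instrument-selection rules to a candidate report
#'
#' Rules are applied in a fixed order and the first failure is recorded:
#' (1) MAF below `maf_min`; (2) Hardy-Weinberg p-value in controls below
#' `hwe_alpha`; (3) instrument-exposure association p-value at or above
#' `exposure_alpha`; (4) any pleiotropy-screen p-value below `screen_alpha`.
#' A rule whose input column is absent or `NA` is skipped for that candidate
#' (e.g. candidates known only by their published MAF). The result does not
#' depend on the row order of `report`.
#'
#' @param report data.frame with column `snp_id` plus any of `maf`, `hwe_p`,
#'   `exposure_p`, `screen_min_p`.
#' @param thresholds named list as [defaultThresholds()].
#' @return `report` with columns `selected` (logical) and `exclusion_reason`
#'   ("MAF", "HWE", "exposure_association", "pleiotropy_screen" or `NA`).
#' @export
selectInstruments <- function(report, thresholds = defaultThresholds()) {
  if (!nrow(report)) stop("empty candidate list")
  getcol <- function(nm) if (nm %in% colnames(report)) report[[nm]] else
    rep(NA_real_, nrow(report))
  maf <- getcol("maf"); hwe <- getcol("hwe_p")
  expP <- getcol("exposure_p"); scr <- getcol("screen_min_p")
  reason <- rep(NA_character_, nrow(report))
  fail <- function(cond) !is.na(cond) & cond
  reason[is.na(reason) & fail(maf < thresholds$maf_min)] <- "MAF"
  reason[is.na(reason) & fail(hwe < thresholds$hwe_alpha)] <- "HWE"
  reason[is.na(reason) & fail(expP >= thresholds$exposure_alpha)] <-
    "exposure_association"
  reason[is.na(reason) & fail(scr < thresholds$screen_alpha)] <-
    "pleiotropy_screen"
  report$selected <- is.na(reason)
  report$exclusion_reason <- reason
  report
}

#' Build and filter the per-candidate instrument report from a cohort
#'
#' For each candidate SNP computes, in controls: the minor allele frequency,
#' the exact Hardy-Weinberg p-value, the instrument-exposure association under
#' the requested genetic model, and the pleiotropy screen across covariates;
#' then applies [selectInstruments()].
#'
#' @inheritParams exposureAssociation
#' @param snps candidate SNP ids (default: all SNPs in the cohort).
#' @param screenCovariates covariates for the pleiotropy screen (default all).
#' @param thresholds selection thresholds ([defaultThresholds()]).
#' @return data.frame: `snp_id`, `maf`, `hwe_p`, `exposure_md`, `exposure_se`,
#'   `exposure_ci_low`, `exposure_ci_high`, `exposure_p`, `percent_diff`,
#'   `screen_min_p`, `selected`, `exclusion_reason`.
#' @export
validateInstruments <- function(cohort, snps = NULL, model = "overdominant",
                                screenCovariates = NULL,
                                thresholds = defaultThresholds(),
                                effectAllele = "alt") {
  if (is.null(snps)) snps <- colnames(genotypeMatrix(cohort))
  if (!length(snps)) stop("empty candidate list")
  ctrl <- controlsOnly(cohort)
  g <- genotypeMatrix(ctrl)
  hasCov <- ncol(covariateData(cohort)) > 0 &&
    (is.null(screenCovariates) || length(screenCovariates) > 0)
  rows <- lapply(snps, function(s) {
    counts <- c(sum(g[, s] == 0L, na.rm = TRUE),
                sum(g[, s] == 1L, na.rm = TRUE),
                sum(g[, s] == 2L, na.rm = TRUE))
    maf <- computeMAF(counts)
    hwe <- suppressWarnings(hweTest(counts)$p.value)
    ea <- tryCatch(
      exposureAssociation(cohort, s, model, effectAllele = effectAllele),
      error = function(e) NULL)
    scr <- if (hasCov) tryCatch(
      pleiotropyScreen(cohort, s, model, covariates = screenCovariates,
                       effectAllele = effectAllele),
      error = function(e) NULL) else NULL
    scrMD <- if (!is.null(scr)) scr[scr$estimand == "md" & !scr$skipped, ] else NULL
    data.frame(
      snp_id = s, maf = maf, hwe_p = hwe,
      exposure_md = if (is.null(ea)) NA_real_ else ea$effect[1L],
      exposure_se = if (is.null(ea)) NA_real_ else ea$se[1L],
      exposure_ci_low = if (is.null(ea)) NA_real_ else ea$ci_low[1L],
      exposure_ci_high = if (is.null(ea)) NA_real_ else ea$ci_high[1L],
      exposure_p = if (is.null(ea)) NA_real_ else ea$p_value[1L],
      percent_diff = if (is.null(ea)) NA_real_ else
        percentDifference(ea$effect[1L]),
      screen_min_p = if (is.null(scrMD) || !nrow(scrMD)) NA_real_ else
        min(scrMD$p_value, na.rm = TRUE),
      stringsAsFactors = FALSE)
  })
  selectInstruments(do.call(rbind, rows), thresholds)
}
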