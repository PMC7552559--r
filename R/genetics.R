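#' Supported genetic models
#'
#' @return character vector of the five genetic-model names. The principal
#'   analysis model is "overdominant" (heterosis: heterozygote vs both
#'   homozygote classes); "dominant", "recessive", "codominant" and "additive"
#'   are the subsidiary models.
#' @export
geneticModels <- function()
  c("overdominant", "dominant", "recessive", "codominant", "additive")

#' Encode genotypes under a genetic model
#'
#' Maps alternate-allele counts to the numeric coding of a genetic model.
#' Missing genotypes propagate as `NA`.
#'
#' @param g numeric vector of alternate-allele counts in \{0, 1, 2, NA\}.
#' @param model one of [geneticModels()].
#' @param effectAllele "alt" (default) or "ref"; with "ref" the allele count
#'   is flipped to `2 - g` before coding.
#' @return for "codominant", a two-column matrix of indicator contrasts
#'   (`het`, `homEffect`) with the zero-effect-allele homozygote as reference;
#'   otherwise a numeric vector: over-dominant 1 for heterozygotes and 0 for
#'   either homozygote; dominant 1 for carriers of the effect allele;
#'   recessive 1 for effect-allele homozygotes; additive the effect-allele
#'   count.
#' @examples
#' encodeGenotype(c(0, 1, 2, NA), "overdominant")
#' encodeGenotype(c(0, 1, 2), "additive", effectAllele = "ref")
#' @export
encodeGenotype <- function(g, model = geneticModels(),
                           effectAllele = c("alt", "ref")) {
  model <- match.arg(model)
  effectAllele <- match.arg(effectAllele)
  g <- as.numeric(g)
  if (any(!g %in% c(0, 1, 2) & !is.na(g)))
    stop("genotypes must be allele counts 0/1/2 or NA")
  if (effectAllele == "ref") g <- 2 - g
  switch(model,
    overdominant = as.numeric(g == 1),
    dominant     = as.numeric(g >= 1),
    recessive    = as.numeric(g == 2),
    additive     = g,
    codominant   = cbind(het = as.numeric(g == 1),
                         homEffect = as.numeric(g == 2))
  )
}

#' Minor allele frequency from genotype counts
#'
#' @param counts numeric length-3 vector `(homRef, het, homAlt)`.
#' @return `min(q, 1 - q)` where `q` is the alternate-allele frequency
#'   `(het + 2 homAlt) / (2 total)`; always in \[0, 0.5\] and invariant under
#'   swapping the ref/alt labels.
#' @examples
#' computeMAF(c(202, 92, 10)) # 112/608
#' @export
computeMAF <- function(counts) {
  counts <- checkGenotypeCounts(counts)
  total <- sum(counts)
  if (total == 0) stop("empty genotype counts")
  q <- (counts[2L] + 2 * counts[3L]) / (2 * total)
  unname(min(q, 1 - q))
}

checkGenotypeCounts <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 3L || anyNA(counts) || any(counts < 0))
    stop("counts must be three non-negative numbers (homRef, het, homAlt)")
  counts
}

#' Hardy-Weinberg equilibrium test
#'
#' Tests genotype counts (conventionally from the control group) against
#' Hardy-Weinberg proportions. The default is the exact conditional test: with
#' allele counts fixed, the p-value is the sum of probabilities of all
#' heterozygote counts whose conditional probability does not exceed that of
#' the observed count. The "chi2" method is the 1-df goodness-of-fit test of
#' observed vs expected genotype counts at the estimated allele frequency.
#'
#' @param counts length-3 vector `(homRef, het, homAlt)`.
#' @param method "exact" (default) or "chi2".
#' @return list with `p.value`, `statistic` (chi-squared statistic, `NA` for
#'   the exact test), `method` and `monomorphic` flag. A monomorphic SNP gives
#'   `p = 1` with a warning.
#' @examples
#' hweTest(c(202, 92, 10), method = "chi2")$statistic # about 0.015
#' hweTest(c(25, 50, 25))$p.value                     # exact HWE proportions
#' @export
hweTest <- function(counts, method = c("exact", "chi2")) {
  method <- match.arg(method)
  counts <- checkGenotypeCounts(counts)
  n <- sum(counts)
  if (n == 0) stop("empty genotype counts")
  nAlt <- counts[2L] + 2 * counts[3L]
  if (nAlt == 0 || nAlt == 2 * n) {
    warning("monomorphic SNP: HWE p-value defined as 1")
    return(list(p.value = 1, statistic = if (method == "chi2") 0 else NA_real_,
                method = method, monomorphic = TRUE))
  }
  if (method == "chi2") {
    q <- nAlt / (2 * n)
    expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
    stat <- sum((counts - expected)^2 / expected)
    list(p.value = pchisq(stat, df = 1, lower.tail = FALSE),
         statistic = stat, method = method, monomorphic = FALSE)
  } else {
    probs <- hweHetProbabilities(n, nAlt)
    pObs <- probs[as.character(counts[2L])]
    if (is.na(pObs)) stop("observed heterozygote count has wrong parity")
    p <- min(1, sum(probs[probs <= pObs * (1 + 1e-12)]))
    list(p.value = p, statistic = NA_real_, method = method,
         monomorphic = FALSE)
  }
}

# Conditional distribution of the heterozygote count given n subjects and
# nAlt alternate alleles (log-factorial form); names are heterozygote counts.
hweHetProbabilities <- function(n, nAlt) {
  nA <- min(nAlt, 2 * n - nAlt)
  hets <- seq.int(nA %% 2, nA, by = 2)
  homMinor <- (nA - hets) / 2
  homMajor <- n - hets - homMinor
  logp <- lgamma(n + 1) - lgamma(homMinor + 1) - lgamma(hets + 1) -
    lgamma(homMajor + 1) + hets * log(2) +
    lgamma(nA + 1) + lgamma(2 * n - nA + 1) - lgamma(2 * n + 1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  names(p) <- hets
  p
}

#' Case-control genotype distribution test
#'
#' Pearson chi-squared test on the 3-by-2 genotype-by-status table. Genotype
#' categories absent in both groups are dropped, reducing the degrees of
#' freedom accordingly.
#'
#' @param countsCases,countsControls length-3 vectors `(homRef, het, homAlt)`.
#' @return list with `statistic`, `df`, `p.value`.
#' @examples
#' genotypeCaseControlTest(c(305, 112, 14), c(202, 92, 10))$p.value
#' @export
genotypeCaseControlTest <- function(countsCases, countsControls) {
  a <- checkGenotypeCounts(countsCases)
  b <- checkGenotypeCounts(countsControls)
  tab <- cbind(cases = a, controls = b)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2L || any(colSums(tab) == 0))
    stop("degenerate genotype-by-status table")
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = unname(ht$p.value))
}

#' Odds ratio from a 2x2 table with Woolf confidence interval
#'
#' @param exposedCases,unexposedCases,exposedControls,unexposedControls cell
#'   counts; "exposed" is carrying the risk genotype (e.g. heterozygote under
#'   the over-dominant model).
#' @param level confidence level (interval uses the 1.96 normal quantile at
#'   the default 0.95).
#' @return list with `or`, `ci` (length 2), `log_or`, `se` and `corrected`
#'   (TRUE when a 0.5 continuity correction was applied because of a zero
#'   cell).
#' @examples
#' contingencyOR(112, 319, 92, 212) # 0.81 (0.58, 1.12)
#' @export
contingencyOR <- function(exposedCases, unexposedCases,
                          exposedControls, unexposedControls,
                          level = 0.95) {
  cells <- c(exposedCases, unexposedCases, exposedControls, unexposedControls)
  if (anyNA(cells) || any(cells < 0)) stop("cells must be non-negative")
  corrected <- any(cells == 0)
  if (corrected) {
    warning("zero cell: 0.5 continuity correction applied")
    cells <- cells + 0.5
  }
  logOR <- log(cells[1L]) + log(cells[4L]) - log(cells[2L]) - log(cells[3L])
  se <- sqrt(sum(1 / cells))
  z <- if (identical(level, 0.95)) 1.96 else qnorm(1 - (1 - level) / 2)
  list(or = exp(logOR), ci = exp(logOR + c(-1, 1) * z * se),
       log_or = logOR, se = se, corrected = corrected)
}

#' Unweighted genetic risk score
#'
#' Counts, per subject, how many instruments carry their risk genotype (here
#' the exposure-lowering genotype: the heterozygote under the over-dominant
#' model).
#'
#' @param genotypes subjects-by-SNPs matrix of allele counts, or an
#'   [MRCohort].
#' @param riskGenotypes named character vector or list mapping SNP id to its
#'   risk genotype, each one of "homRef", "het", "homAlt".
#' @param minCallRate minimum fraction of non-missing instrument genotypes a
#'   subject needs for a score; below it the score is `NA`. With the default 1
#'   any missing instrument genotype gives a missing score. Scores are rescaled
#'   from the observed instruments: `J * mean(indicator)` rounded to the
#'   nearest integer when some genotypes are missing but the call rate is met.
#' @return integer vector of scores in `0..J`.
#' @examples
#' g <- cbind(rs1 = c(1, 0, 1), rs2 = c(1, 2, NA))
#' buildGRS(g, c(rs1 = "het", rs2 = "het"))
#' @export
buildGRS <- function(genotypes, riskGenotypes, minCallRate = 1) {
  if (is(genotypes, "MRCohort")) genotypes <- genotypeMatrix(genotypes)
  genotypes <- as.matrix(genotypes)
  snps <- names(riskGenotypes)
  if (is.null(snps) || !length(snps)) stop("riskGenotypes must be named by SNP")
  missing <- setdiff(snps, colnames(genotypes))
  if (length(missing))
    stop(sprintf("unknown SNP(s) in risk definitions: %s",
                 paste(missing, collapse = ", ")))
  codeFor <- c(homRef = 0, het = 1, homAlt = 2)
  risk <- codeFor[unlist(riskGenotypes, use.names = FALSE)]
  if (anyNA(risk)) stop("risk genotypes must be homRef, het or homAlt")
  ind <- vapply(seq_along(snps), function(j)
    as.numeric(genotypes[, snps[j]] == risk[j]), numeric(nrow(genotypes)))
  ind <- matrix(ind, nrow = nrow(genotypes))
  J <- length(snps)
  called <- rowSums(!is.na(ind))
  score <- ifelse(called / J >= minCallRate & called > 0,
                  round(J * rowMeans(ind, na.rm = TRUE)), NA_real_)
  as.integer(score)
}
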