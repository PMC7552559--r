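#' Genotype distributions from the motivating case-control study
#'
#' Published genotype counts for the eight candidate SNPs that passed the
#' minor-allele-frequency filter in the motivating study of leukocyte telomere
#' length and ischemic stroke in a Han Chinese population (431 first-ever
#' ischemic stroke cases, 304 healthy controls). Counts are per genotype
#' category with the reference homozygote first; these printed counts are the
#' inputs from which the unadjusted over-dominant odds ratios and
#' Hardy-Weinberg statistics are recomputed.
#'
#' @return data.frame with columns `snp_id`, `chromosome`, `gene`,
#'   `ref_allele`, `alt_allele`, `controls_homRef`, `controls_het`,
#'   `controls_homAlt`, `cases_homRef`, `cases_het`, `cases_homAlt`.
#' @export
studyGenotypeCounts <- function() {
  data.frame(
    snp_id = c("rs11125529", "rs10936599", "rs7726159", "rs17653722",
               "rs8105767", "rs409627", "rs412658", "rs755017"),
    chromosome = c("2", "3", "5", "12", "19", "19", "19", "20"),
    gene = c("ACYP2", "MYNN", "TERT", "KRT80", "LOC112268248", "ZNF676",
             "ZNF676", "ZBTB46"),
    ref_allele = c("C", "T", "C", "G", "A", "G", "C", "A"),
    alt_allele = c("A", "C", "A", "T", "G", "C", "T", "G"),
    controls_homRef = c(202, 103, 114, 220, 159, 129, 130, 102),
    controls_het    = c(92, 148, 147, 76, 125, 145, 143, 147),
    controls_homAlt = c(10, 53, 43, 8, 20, 30, 31, 55),
    cases_homRef = c(305, 121, 155, 302, 215, 189, 188, 163),
    cases_het    = c(112, 225, 195, 117, 177, 192, 190, 199),
    cases_homAlt = c(14, 85, 81, 12, 39, 50, 53, 69),
    stringsAsFactors = FALSE
  )
}

#' Candidate SNP panel with published minor allele frequencies
#'
#' The twelve telomere-length-associated SNPs screened as candidate
#' instruments, with the minor allele frequencies observed in the study. Four
#' SNPs fall below the MAF 0.05 filter; the remaining eight have frequencies
#' derived from the published genotype counts ([studyGenotypeCounts()]).
#'
#' @return data.frame with columns `snp_id` and `maf`.
#' @export
studyCandidateMAFs <- function() {
  counts <- studyGenotypeCounts()
  ctrl <- as.matrix(counts[, c("controls_homRef", "controls_het",
                               "controls_homAlt")])
  passing <- data.frame(
    snp_id = counts$snp_id,
    maf = apply(ctrl, 1L, computeMAF),
    stringsAsFactors = FALSE
  )
  failing <- data.frame(
    snp_id = c("rs6772228", "rs9420907", "rs3027234", "rs6028466"),
    maf = c(0.000, 0.006, 0.042, 0.002),
    stringsAsFactors = FALSE
  )
  out <- rbind(passing, failing)
  out[order(out$snp_id), , drop = FALSE]
}

#' Published per-instrument summary associations
#'
#' Summary statistics for the two instruments retained in the motivating
#' study, under the over-dominant model: the mean difference in ln telomere
#' length for heterozygote carriers among controls (with 95 percent CI) and
#' the unadjusted odds ratio of ischemic stroke (with 95 percent CI). Standard
#' errors are recovered from the intervals as `(high - low) / (2 * 1.96)`;
#' outcome effects are converted to the log-odds scale. These feed the linear
#' MR estimators via [ivwEstimate()] and friends.
#'
#' @return data.frame with columns `snp_id`, `beta_x`, `se_x`, `beta_y`,
#'   `se_y` (ln-exposure and log-odds scales).
#' @export
studyInstrumentSummary <- function() {
  data.frame(
    snp_id = c("rs11125529", "rs412658"),
    beta_x = c(-0.108, -0.089),
    se_x = c(seFromCI(-0.204, -0.013), seFromCI(-0.176, -0.001)),
    beta_y = c(log(0.810), log(0.890)),
    se_y = c(seFromCI(log(0.580), log(1.120)),
             seFromCI(log(0.660), log(1.190))),
    stringsAsFactors = FALSE
  )
}

#' Recover a standard error from a 95 percent confidence interval
#'
#' @param low,high interval endpoints on the scale of the estimate.
#' @return `(high - low) / (2 * 1.96)`.
#' @export
seFromCI <- function(low, high) {
  if (any(high < low)) stop("interval endpoints out of order")
  (high - low) / (2 * 1.96)
}
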