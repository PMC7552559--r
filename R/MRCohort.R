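#' Construct a case-control MR cohort
#'
#' Bundles genotypes, outcome, exposure and covariates into an [MRCohort]
#' object, the unit all pipeline stages operate on.
#'
#' @param genotypes subjects-by-SNPs matrix or data.frame of alternate-allele
#'   counts (0/1/2, `NA` missing); column names are SNP ids, row names (if
#'   present) subject ids.
#' @param outcome binary vector, 1 = case (here: ischemic stroke).
#' @param exposure numeric vector of ln-scale exposure values (ln telomere
#'   length, ln-kb); `NA` allowed.
#' @param covariates data.frame of per-subject covariates (may be empty).
#' @param snpInfo optional data.frame of per-SNP metadata; must contain
#'   `snp_id` matching the genotype columns. Columns `chromosome`, `gene`,
#'   `ref_allele`, `alt_allele` are filled with placeholders when absent.
#' @param metadata optional list stored in the object metadata (e.g. the
#'   simulation seed).
#' @return an [MRCohort].
#' @examples
#' g <- matrix(c(0, 1, 2, 1), 2, 2, dimnames = list(NULL, c("rs1", "rs2")))
#' MRCohort(g, outcome = c(1, 0), exposure = c(1.9, 2.0))
#' @export
MRCohort <- function(genotypes, outcome, exposure,
                     covariates = data.frame(), snpInfo = NULL,
                     metadata = list()) {
  g <- as.matrix(genotypes)
  storage.mode(g) <- "integer"
  if (is.null(colnames(g)))
    stop("genotype columns must be named by SNP id")
  n <- nrow(g)
  if (length(outcome) != n || length(exposure) != n)
    stop("outcome/exposure length must match the number of subjects")
  subj <- rownames(g)
  if (is.null(subj)) subj <- sprintf("S%04d", seq_len(n))
  if (anyDuplicated(subj)) stop("duplicate subject ids")
  if (!all(outcome %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (sum(outcome == 1) < 1 || sum(outcome == 0) < 1)
    stop("cohort needs at least one case and one control")
  if (nrow(covariates) && nrow(covariates) != n)
    stop("covariates must have one row per subject")
  cd <- S4Vectors::DataFrame(outcome = as.integer(outcome),
                             exposure = as.numeric(exposure),
                             row.names = subj)
  if (nrow(covariates))
    cd <- cbind(cd, S4Vectors::DataFrame(covariates, row.names = subj))
  if (is.null(snpInfo)) snpInfo <- data.frame(snp_id = colnames(g))
  if (!"snp_id" %in% colnames(snpInfo)) stop("snpInfo needs a snp_id column")
  snpInfo <- snpInfo[match(colnames(g), snpInfo$snp_id), , drop = FALSE]
  if (anyNA(snpInfo$snp_id))
    stop("snpInfo does not cover all genotype columns")
  for (col in c("chromosome", "gene"))
    if (is.null(snpInfo[[col]])) snpInfo[[col]] <- NA_character_
  if (is.null(snpInfo$ref_allele)) snpInfo$ref_allele <- "A"
  if (is.null(snpInfo$alt_allele)) snpInfo$alt_allele <- "G"
  rd <- S4Vectors::DataFrame(snpInfo, row.names = snpInfo$snp_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(genotype = t(g)), colData = cd, rowData = rd,
    metadata = metadata)
  methods::new("MRCohort", se)
}

#' Accessors for MRCohort
#'
#' @param x an [MRCohort].
#' @return `caseStatus`: integer 0/1 vector; `exposureValues`: numeric vector;
#'   `genotypeMatrix`: subjects-by-SNPs integer matrix; `covariateData`:
#'   data.frame of covariates (outcome and exposure columns excluded);
#'   `snpInfo`: data.frame of per-SNP metadata.
#' @name MRCohort-accessors
NULL

#' @rdname MRCohort-accessors
#' @export
setMethod("caseStatus", "MRCohort", function(x)
  SummarizedExperiment::colData(x)$outcome)

#' @rdname MRCohort-accessors
#' @export
setMethod("exposureValues", "MRCohort", function(x)
  SummarizedExperiment::colData(x)$exposure)

#' @rdname MRCohort-accessors
#' @export
setMethod("genotypeMatrix", "MRCohort", function(x)
  t(SummarizedExperiment::assay(x, "genotype")))

#' @rdname MRCohort-accessors
#' @export
setMethod("covariateData", "MRCohort", function(x) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  cd[, setdiff(colnames(cd), c("outcome", "exposure")), drop = FALSE]
})

#' @rdname MRCohort-accessors
#' @export
setMethod("snpInfo", "MRCohort", function(x)
  as.data.frame(SummarizedExperiment::rowData(x)))

#' @rdname MRCohort-class
#' @param object an `MRCohort`.
#' @export
setMethod("show", "MRCohort", function(object) {
  y <- caseStatus(object)
  cat(sprintf("MRCohort: %d subjects (%d cases / %d controls), %d SNPs\n",
              ncol(object), sum(y == 1L), sum(y == 0L), nrow(object)))
  cat(sprintf("  exposure (ln scale): median %.3f [%.3f, %.3f], %d missing\n",
              median(exposureValues(object), na.rm = TRUE),
              min(exposureValues(object), na.rm = TRUE),
              max(exposureValues(object), na.rm = TRUE),
              sum(is.na(exposureValues(object)))))
  cv <- covariateData(object)
  cat(sprintf("  covariates: %s\n",
              if (ncol(cv)) paste(colnames(cv), collapse = ", ") else "none"))
  cat(sprintf("  SNPs: %s\n", paste(head(rownames(object), 8), collapse = ", ")))
})

#' Restrict a cohort to controls
#'
#' Instrument-exposure and pleiotropy analyses are run in disease-free
#' subjects only, to avoid reverse-causation from the outcome.
#'
#' @param x an [MRCohort].
#' @return an [MRCohort] containing only control subjects.
#' @export
controlsOnly <- function(x) {
  stopifnot(is(x, "MRCohort"))
  x[, caseStatus(x) == 0L]
}
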