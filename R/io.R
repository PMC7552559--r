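writeTSV <- function(df, path)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")

#' Write a cohort to delimited files
#'
#' Writes a phenotype table (`phenotype.tsv`: `subject_id`, `outcome`,
#' `exposure`, covariates; missing as "NA"), genotypes (`genotypes.tsv`,
#' subjects by SNPs allele counts 0/1/2, or a minimal VCF 4.2 with GT fields),
#' and `meta.yaml` recording the seed and sample sizes.
#'
#' @param cohort an [MRCohort].
#' @param dir output directory (created if needed).
#' @param genotypeFormat "tsv" (default) or "vcf".
#' @return invisibly, the named vector of file paths.
#' @export
writeCohort <- function(cohort, dir, genotypeFormat = c("tsv", "vcf")) {
  genotypeFormat <- match.arg(genotypeFormat)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- genotypeMatrix(cohort)
  ph <- data.frame(subject_id = rownames(g), outcome = caseStatus(cohort),
                   exposure = exposureValues(cohort),
                   covariateData(cohort), stringsAsFactors = FALSE)
  phPath <- file.path(dir, "phenotype.tsv")
  writeTSV(ph, phPath)
  if (genotypeFormat == "tsv") {
    gtPath <- file.path(dir, "genotypes.tsv")
    writeTSV(cbind(data.frame(subject_id = rownames(g)), as.data.frame(g)),
             gtPath)
  } else {
    gtPath <- file.path(dir, "genotypes.vcf")
    writeGenotypeVCF(cohort, gtPath)
  }
  meta <- S4Vectors::metadata(cohort)
  metaPath <- file.path(dir, "meta.yaml")
  yaml::write_yaml(list(seed = meta$seed,
                        n_cases = sum(caseStatus(cohort) == 1L),
                        n_controls = sum(caseStatus(cohort) == 0L),
                        snps = colnames(g)), metaPath)
  invisible(c(phenotype = phPath, genotype = gtPath, meta = metaPath))
}

#' Write genotypes as a minimal VCF 4.2
#'
#' One biallelic SNP record per row with GT fields ("0/0", "0/1", "1/1",
#' "./." for missing); positions fall back to the SNP index when no
#' coordinate metadata is present.
#'
#' @param cohort an [MRCohort].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeGenotypeVCF <- function(cohort, path) {
  g <- genotypeMatrix(cohort)
  info <- snpInfo(cohort)
  gtOf <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(g)), collapse = "\t"))
  for (j in seq_len(ncol(g))) {
    gt <- gtOf[as.character(g[, j])]
    gt[is.na(gt)] <- "./."
    chrom <- info$chromosome[j]
    if (is.na(chrom)) chrom <- "1"
    lines <- c(lines, paste(c(chrom, j, colnames(g)[j], info$ref_allele[j],
                              info$alt_allele[j], ".", ".", ".", "GT", gt),
                            collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

# Genotype matrix (subjects x SNPs allele counts) from a VCF via vcfR.
readGenotypeVCF <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  counts <- apply(gt, c(1, 2), function(v) {
    if (is.na(v)) return(NA_integer_)
    alleles <- strsplit(v, "[/|]")[[1L]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(alleles != "0")
  })
  fix <- vcfR::getFIX(vcf)
  out <- t(counts)
  colnames(out) <- unname(fix[, "ID"])
  list(genotypes = out,
       info = data.frame(snp_id = unname(fix[, "ID"]),
                         chromosome = unname(fix[, "CHROM"]),
                         ref_allele = unname(fix[, "REF"]),
                         alt_allele = unname(fix[, "ALT"]),
                         stringsAsFactors = FALSE))
}

#' Read a cohort from phenotype and genotype files
#'
#' Joins a phenotype table (TSV with header; columns `subject_id`, `outcome`,
#' `exposure`, plus covariates) with genotypes from either a subjects-by-SNPs
#' TSV of allele counts (0/1/2, "NA" missing) or a VCF 4.2 ("./." becomes
#' missing). Subjects present in only one file are reported and dropped.
#'
#' @param phenotypePath path to the phenotype TSV.
#' @param genotypePath path to the genotype TSV or `.vcf`.
#' @param snps optional SNP ids that must be present; an absent SNP is an
#'   error naming it.
#' @return an [MRCohort].
#' @export
readCohort <- function(phenotypePath, genotypePath, snps = NULL) {
  ph <- read.delim(phenotypePath, check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("subject_id", "outcome", "exposure")
  if (!all(need %in% colnames(ph)))
    stop("phenotype table needs subject_id, outcome, exposure columns")
  if (anyDuplicated(ph$subject_id)) stop("duplicate subject ids in phenotype")
  if (!all(ph$outcome %in% c(0L, 1L)))
    stop("outcome is not binary 0/1")
  if (grepl("\\.vcf$", genotypePath, ignore.case = TRUE)) {
    gv <- readGenotypeVCF(genotypePath)
    g <- gv$genotypes
    info <- gv$info
  } else {
    gt <- read.delim(genotypePath, check.names = FALSE,
                     stringsAsFactors = FALSE)
    if (!"subject_id" %in% colnames(gt))
      stop("genotype table needs a subject_id column")
    if (anyDuplicated(gt$subject_id))
      stop("duplicate subject ids in genotypes")
    g <- as.matrix(gt[, setdiff(colnames(gt), "subject_id"), drop = FALSE])
    rownames(g) <- gt$subject_id
    info <- NULL
  }
  if (!is.null(snps)) {
    absent <- setdiff(snps, colnames(g))
    if (length(absent))
      stop(sprintf("genotype source is missing SNP(s): %s",
                   paste(absent, collapse = ", ")))
  }
  common <- intersect(ph$subject_id, rownames(g))
  unmatched <- length(ph$subject_id) + nrow(g) - 2L * length(common)
  if (unmatched)
    message(sprintf("%d subject(s) present in only one file were dropped",
                    unmatched))
  if (!length(common)) stop("no subjects shared between the two files")
  ph <- ph[match(common, ph$subject_id), , drop = FALSE]
  g <- g[common, , drop = FALSE]
  covars <- ph[, setdiff(colnames(ph), need), drop = FALSE]
  rownames(covars) <- common
  MRCohort(g, outcome = ph$outcome, exposure = ph$exposure,
           covariates = covars, snpInfo = info)
}

#' Construct a pipeline run configuration
#'
#' @param simulation a [SimulationConfig], or `NULL` when reading inputs.
#' @param phenotypePath,genotypePath input files (ignored when simulating).
#' @param candidateSnps candidate instrument SNP ids (default: all SNPs).
#' @param geneticModel genetic model (default "overdominant").
#' @param covariates covariates for outcome-stage adjustment and the
#'   pleiotropy screen.
#' @param thresholds QC thresholds ([defaultThresholds()]).
#' @param K strata for the non-linear stage (default 5).
#' @param nBoot mode-based-estimator bootstrap replicates.
#' @param seed run seed; all stochastic sub-stages derive their seeds from it.
#' @return a [RunConfig].
#' @export
runConfig <- function(simulation = NULL, phenotypePath = "",
                      genotypePath = "", candidateSnps = character(),
                      geneticModel = "overdominant",
                      covariates = character(),
                      thresholds = defaultThresholds(), K = 5L,
                      nBoot = 1000L, seed = 1L) {
  methods::new("RunConfig",
    simulation = if (is.null(simulation)) list() else list(simulation),
    phenotypePath = phenotypePath, genotypePath = genotypePath,
    candidateSnps = candidateSnps, geneticModel = geneticModel,
    covariates = covariates, thresholds = thresholds,
    K = as.integer(K), nBoot = as.integer(nBoot), seed = as.integer(seed))
}

#' Read a run configuration from a YAML file
#'
#' Recognized keys: `simulation` (with `n_cases`, `n_controls`, `snps` (list
#' of `snp_id`/`maf`/`delta`), `exposure_mean`, `exposure_sd`, `causal_shape`,
#' `theta`, `theta2`, `threshold`, `baseline_log_odds`, `use_default_covariates`),
#' or `phenotype`/`genotype` paths; plus `candidate_snps`, `genetic_model`,
#' `covariates`, `thresholds`, `k_strata`, `n_boot`, `seed`.
#'
#' @param path YAML file path.
#' @return a [RunConfig].
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulation)) {
    s <- y$simulation
    snps <- do.call(rbind, lapply(s$snps, function(r)
      data.frame(snp_id = r$snp_id, maf = r$maf, delta = r$delta,
                 geneticModel = if (is.null(r$genetic_model)) "overdominant"
                 else r$genetic_model, stringsAsFactors = FALSE)))
    sim <- SimulationConfig(
      nCases = s$n_cases, nControls = s$n_controls, snps = snps,
      exposureMean = s$exposure_mean %||% 1.91,
      exposureSd = s$exposure_sd %||% 0.30,
      covariates = if (isTRUE(s$use_default_covariates))
        defaultCovariateSpec() else data.frame(),
      causalShape = s$causal_shape %||% "null",
      theta = s$theta %||% 0, theta2 = s$theta2 %||% 0,
      threshold = s$threshold %||% 1.91,
      baselineLogOdds = s$baseline_log_odds %||% -0.5,
      seed = y$seed %||% 1L)
  }
  thr <- defaultThresholds()
  for (nm in names(y$thresholds %||% list())) thr[[nm]] <- y$thresholds[[nm]]
  runConfig(simulation = sim,
            phenotypePath = y$phenotype %||% "",
            genotypePath = y$genotype %||% "",
            candidateSnps = as.character(unlist(y$candidate_snps)),
            geneticModel = y$genetic_model %||% "overdominant",
            covariates = as.character(unlist(y$covariates)),
            thresholds = thr, K = y$k_strata %||% 5L,
            nBoot = y$n_boot %||% 1000L, seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full one-sample MR pipeline
#'
#' Executes genotype QC and instrument selection, per-instrument summary
#' associations, linear MR by the three estimators, genetic risk score
#' construction, semiparametric non-linear MR with the three non-linearity
#' tests and causal curves, and the observational analyses; writes every
#' stage's table to `outDir` as TSV plus a run log recording seeds and
#' exclusions. With zero selected instruments the MR stages are skipped with a
#' structured message and partial outputs (QC, observational) are retained.
#'
#' @param config a [RunConfig] (see [runConfig()], [readRunConfig()]).
#' @param outDir output directory.
#' @return invisibly, a list with elements `cohort`, `qc`, `summary`,
#'   `linear`, `nonlinear`, `observational`, `status` ("ok" or
#'   "no_instruments") and `files`.
#' @export
runPipeline <- function(config, outDir) {
  stopifnot(is(config, "RunConfig"))
  methods::validObject(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log <- c(sprintf("run seed: %d", config@seed),
           sprintf("genetic model: %s", config@geneticModel))
  if (length(config@simulation)) {
    sim <- config@simulation[[1L]]
    sim@seed <- config@seed
    cohort <- simulateCohort(sim)
    writeCohort(cohort, file.path(outDir, "cohort"))
    log <- c(log, sprintf("simulated cohort: %d cases / %d controls (seed %d)",
                          sum(caseStatus(cohort) == 1L),
                          sum(caseStatus(cohort) == 0L), config@seed))
  } else {
    cohort <- readCohort(config@phenotypePath, config@genotypePath,
                         snps = config@candidateSnps)
    log <- c(log, sprintf("read cohort from %s + %s",
                          config@phenotypePath, config@genotypePath))
  }
  snps <- if (length(config@candidateSnps)) config@candidateSnps else
    colnames(genotypeMatrix(cohort))
  covs <- intersect(config@covariates, colnames(covariateData(cohort)))
  qc <- suppressWarnings(validateInstruments(
    cohort, snps, model = config@geneticModel,
    screenCovariates = if (length(covs)) covs else NULL,
    thresholds = config@thresholds))
  files <- c(qc = file.path(outDir, "qc_instruments.tsv"))
  writeTSV(qc, files[["qc"]])
  for (i in which(!qc$selected))
    log <- c(log, sprintf("excluded %s: %s", qc$snp_id[i],
                          qc$exclusion_reason[i]))
  desc <- describeAndTest(cohort)
  files["descriptives"] <- file.path(outDir, "descriptives.tsv")
  writeTSV(desc, files[["descriptives"]])
  obs <- list(descriptives = desc)
  if (sum(!is.na(exposureValues(cohort))) >= 50L) {
    obs$regression <- adjustedExposureRegression(cohort, covs)
    obs$quintiles <- quintileComparison(cohort)
    files["observational_regression"] <-
      file.path(outDir, "observational_regression.tsv")
    writeTSV(obs$regression, files[["observational_regression"]])
    files["quintiles"] <- file.path(outDir, "quintile_comparison.tsv")
    writeTSV(obs$quintiles, files[["quintiles"]])
  }
  sel <- qc$snp_id[qc$selected]
  if (!length(sel)) {
    log <- c(log, "no instruments selected: MR stages aborted")
    writeLines(log, file.path(outDir, "run_log.txt"))
    message("no instruments passed selection; MR stages skipped")
    return(invisible(list(cohort = cohort, qc = qc, summary = NULL,
                          linear = NULL, nonlinear = NULL,
                          observational = obs, status = "no_instruments",
                          files = files)))
  }
  log <- c(log, sprintf("selected instruments: %s", paste(sel, collapse = ", ")))
  summ <- summaryAssociations(cohort, sel, model = config@geneticModel,
                              outcomeCovariates = covs)
  files["summary"] <- file.path(outDir, "summary_associations.tsv")
  writeTSV(summ, files[["summary"]])
  mbeSeed <- config@seed + 1000L
  log <- c(log, sprintf("mode-based estimator bootstrap seed: %d", mbeSeed))
  est <- list(ivwEstimate(summ), mlEstimate(summ),
              suppressWarnings(mbeEstimate(summ, nBoot = config@nBoot,
                                           seed = mbeSeed)))
  linear <- do.call(rbind, lapply(est, function(e) data.frame(
    method = e@method, theta = e@theta, se = e@se, ci_low = e@ci[1L],
    ci_high = e@ci[2L], or_per_10pct_decrease = e@orPer10,
    or_ci_low = e@orCI[1L], or_ci_high = e@orCI[2L],
    n_instruments = e@nInstruments, stringsAsFactors = FALSE)))
  files["linear"] <- file.path(outDir, "linear_mr_estimates.tsv")
  writeTSV(linear, files[["linear"]])
  risk <- setNames(rep("het", length(sel)), sel)
  grs <- buildGRS(cohort, risk)
  log <- c(log, "GRS: unweighted count of heterozygous (exposure-lowering) genotypes")
  nl <- tryCatch(
    nonlinearMR(cohort, grs, K = config@K, covariates = covs),
    error = function(e) {
      log <<- c(log, sprintf("non-linear stage failed: %s",
                             conditionMessage(e)))
      NULL
    })
  if (!is.null(nl)) {
    files["strata"] <- file.path(outDir, "lace_strata.tsv")
    writeTSV(laceTable(nl), files[["strata"]])
    files["nonlinear_tests"] <- file.path(outDir, "nonlinear_tests.tsv")
    writeTSV(nonlinearityTests(nl), files[["nonlinear_tests"]])
    files["curves"] <- file.path(outDir, "causal_curves.tsv")
    writeTSV(do.call(rbind, causalCurves(nl)), files[["curves"]])
  }
  writeLines(log, file.path(outDir, "run_log.txt"))
  invisible(list(cohort = cohort, qc = qc, summary = summ, linear = linear,
                 nonlinear = nl, observational = obs, status = "ok",
                 files = files))
}
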