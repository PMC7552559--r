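test_that("percent difference transform evaluates the published formula", {
  expect_equal(percentDifference(0), 0)
  expect_equal(percentDifference(-0.108), (exp(-0.108) - 1) * 100)
  expect_equal(round(percentDifference(-0.108), 2), -10.24)
  expect_equal(percentDifference(log(2)), 100)
  expect_error(percentDifference(Inf), "finite")
  # monotone, and asymmetric around zero
  b <- seq(-1, 1, by = 0.1)
  expect_true(all(diff(percentDifference(b)) > 0))
  expect_false(isTRUE(all.equal(percentDifference(-0.5),
                                -percentDifference(0.5))))
})

test_that("exposure association recovers the simulated over-dominant effect", {
  delta <- -0.10
  snps <- data.frame(snp_id = "s1", maf = 0.3, delta = delta,
                     geneticModel = "overdominant")
  est <- vapply(1:25, function(r) {
    cfg <- plainConfig(seed = 300 + r, nCases = 200, nControls = 4000,
                       snps = snps)
    exposureAssociation(simulateCohort(cfg), "s1")$effect
  }, numeric(1))
  mcse <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - delta), 3 * mcse)
})

test_that("exposure association p-values are uniform under the genetic null", {
  snps <- data.frame(snp_id = "s1", maf = 0.3, delta = 0,
                     geneticModel = "overdominant")
  p <- vapply(1:200, function(r) {
    cfg <- plainConfig(seed = 700 + r, nCases = 50, nControls = 400,
                       snps = snps)
    exposureAssociation(simulateCohort(cfg), "s1")$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("degenerate designs are reported", {
  coh <- tinyCohort()
  expect_error(exposureAssociation(coh, "nope"), "not present")
  g <- cbind(rs1 = rep(0L, 40), rs2 = rep(c(0L, 1L), 20))
  x <- rnorm(40)
  coh2 <- MRCohort(g, outcome = rep(c(1, 0), 20), exposure = x)
  expect_error(exposureAssociation(coh2, "rs1", controls = FALSE),
               "constant")
  # constant exposure: zero effect, p defined as 1
  coh3 <- MRCohort(g, outcome = rep(c(1, 0), 20), exposure = rep(2, 40))
  ea <- exposureAssociation(coh3, "rs2", controls = FALSE)
  expect_equal(ea$effect, 0)
  expect_equal(ea$p_value, 1)
})

test_that("pleiotropy screen flags a deterministic genotype-covariate link", {
  set.seed(21)
  n <- 400
  g <- cbind(rs1 = rbinom(n, 2, 0.4))
  code <- as.numeric(g[, 1] == 1)
  coh <- MRCohort(g, outcome = rbinom(n, 1, 0.4), exposure = rnorm(n, 1.9),
                  covariates = data.frame(copy = code, noise = rnorm(n)))
  scr <- suppressWarnings(pleiotropyScreen(coh, "rs1"))
  expect_lt(scr$p_value[scr$covariate == "copy" & scr$estimand == "md"], 1e-6)
  # binary covariates are reported on both scales
  coh2 <- MRCohort(g, outcome = rbinom(n, 1, 0.4), exposure = rnorm(n, 1.9),
                   covariates = data.frame(sex = rbinom(n, 1, 0.5)))
  scr2 <- pleiotropyScreen(coh2, "rs1")
  expect_setequal(scr2$estimand, c("md", "logodds"))
  expect_warning(
    scr3 <- pleiotropyScreen(
      MRCohort(g, outcome = rbinom(n, 1, 0.4), exposure = rnorm(n, 1.9),
               covariates = data.frame(flat = rep(1, n))), "rs1"),
    "constant")
  expect_true(scr3$skipped)
})

test_that("pleiotropy screen has roughly nominal type-I error under the null", {
  snps <- data.frame(snp_id = "s1", maf = 0.35, delta = -0.1,
                     geneticModel = "overdominant")
  hits <- total <- 0L
  for (r in 1:40) {
    cfg <- SimulationConfig(nCases = 80, nControls = 320, snps = snps,
                            covariates = defaultCovariateSpec()[1:6, ],
                            seed = 900 + r)
    scr <- pleiotropyScreen(simulateCohort(cfg), "s1")
    scr <- scr[scr$estimand == "md", ]
    hits <- hits + sum(scr$p_value < 0.05)
    total <- total + nrow(scr)
  }
  expect_gt(hits / total, 0.01)
  expect_lt(hits / total, 0.10)
})

test_that("instrument selection applies rules in order, stably", {
  rep0 <- data.frame(
    snp_id = c("a", "b", "c", "d", "e"),
    maf = c(0.01, 0.2, 0.2, 0.2, 0.2),
    hwe_p = c(0.001, 0.001, 0.5, 0.5, 0.5),
    exposure_p = c(0.9, 0.01, 0.5, 0.01, 0.01),
    screen_min_p = c(1e-4, 0.5, 0.5, 1e-4, 0.5))
  sel <- selectInstruments(rep0)
  expect_equal(sel$exclusion_reason,
               c("MAF", "HWE", "exposure_association", "pleiotropy_screen", NA))
  expect_equal(sel$snp_id[sel$selected], "e")
  # permuting candidates never changes the selected set
  perm <- sample(nrow(rep0))
  sel2 <- selectInstruments(rep0[perm, ])
  expect_setequal(sel2$snp_id[sel2$selected], sel$snp_id[sel$selected])
  expect_error(selectInstruments(rep0[0, ]), "empty")
  # monomorphic candidates are all excluded at the MAF rule
  mono <- data.frame(snp_id = c("x", "y"), maf = c(0, 0))
  selM <- selectInstruments(mono)
  expect_false(any(selM$selected))
  expect_equal(unique(selM$exclusion_reason), "MAF")
})

test_that("strong simulated instruments survive validation", {
  snps <- data.frame(snp_id = c("s1", "s2"), maf = c(0.3, 0.4), delta = -0.15,
                     geneticModel = "overdominant")
  # frequency / equilibrium / exposure rules never reject strong instruments
  kept <- vapply(1:5, function(r) {
    cfg <- SimulationConfig(nCases = 2000, nControls = 3000, snps = snps,
                            covariates = defaultCovariateSpec()[1:4, ],
                            seed = 40 + r)
    qc <- suppressWarnings(validateInstruments(simulateCohort(cfg),
                                               screenCovariates = character()))
    sum(qc$selected)
  }, numeric(1))
  expect_true(all(kept == 2))
  # with the covariate screen on, only the screen can exclude them, at
  # roughly its per-covariate false-positive rate
  cfg <- SimulationConfig(nCases = 2000, nControls = 3000, snps = snps,
                          covariates = defaultCovariateSpec()[1:4, ],
                          seed = 46)
  qc <- suppressWarnings(validateInstruments(simulateCohort(cfg)))
  expect_true(all(is.na(qc$exclusion_reason) |
                    qc$exclusion_reason == "pleiotropy_screen"))
})
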