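test_that("genotype encoding follows each genetic model", {
  g <- c(0, 1, 2, NA)
  expect_equal(encodeGenotype(g, "overdominant"), c(0, 1, 0, NA))
  expect_equal(encodeGenotype(g, "dominant"), c(0, 1, 1, NA))
  expect_equal(encodeGenotype(g, "recessive"), c(0, 0, 1, NA))
  expect_equal(encodeGenotype(g, "additive"), c(0, 1, 2, NA))
  cod <- encodeGenotype(g, "codominant")
  expect_equal(cod[, "het"], c(0, 1, 0, NA))
  expect_equal(cod[, "homEffect"], c(0, 0, 1, NA))
  # flipping the effect allele mirrors the count
  expect_equal(encodeGenotype(c(0, 1, 2), "additive", effectAllele = "ref"),
               c(2, 1, 0))
  expect_equal(encodeGenotype(c(2, 2), "recessive", effectAllele = "ref"),
               c(0, 0))
  # an all-reference sample codes to zero under every model
  for (m in setdiff(geneticModels(), "codominant"))
    expect_true(all(encodeGenotype(rep(0, 5), m) == 0))
  expect_error(encodeGenotype(c(0, 3), "additive"), "allele counts")
  expect_error(encodeGenotype(c(0, 1), "banana"))
})

test_that("minor allele frequency matches hand counts and is label-invariant", {
  expect_equal(computeMAF(c(202, 92, 10)), 112 / 608)
  expect_equal(computeMAF(c(100, 0, 0)), 0)
  expect_equal(computeMAF(c(25, 50, 25)), 0.5)
  expect_error(computeMAF(c(0, 0, 0)), "empty")
  set.seed(5)
  for (i in 1:25) {
    counts <- rmultinom(1, 200, runif(3))[, 1]
    m <- computeMAF(counts)
    expect_gte(m, 0); expect_lte(m, 0.5)
    expect_equal(m, computeMAF(rev(counts)))
  }
})

test_that("HWE chi-squared test matches the expected-count formula", {
  perfect <- hweTest(c(25, 50, 25), method = "chi2")
  expect_equal(perfect$statistic, 0, tolerance = 1e-12)
  expect_equal(perfect$p.value, 1)
  h <- hweTest(c(202, 92, 10), method = "chi2")
  # independent recomputation from HWE-expected counts at q = 112/608
  q <- 112 / 608
  e <- 304 * c((1 - q)^2, 2 * q * (1 - q), q^2)
  expect_equal(h$statistic, sum((c(202, 92, 10) - e)^2 / e), tolerance = 1e-12)
  expect_equal(h$statistic, 0.0145, tolerance = 1e-2)
  expect_lt(hweTest(c(50, 0, 50), method = "chi2")$p.value, 1e-3)
  expect_lt(hweTest(c(50, 0, 50), method = "exact")$p.value, 1e-3)
  expect_warning(mono <- hweTest(c(100, 0, 0)), "monomorphic")
  expect_equal(mono$p.value, 1)
})

test_that("exact HWE test matches full enumeration for 2n <= 100", {
  cases <- list(c(20, 20, 10), c(30, 10, 2), c(5, 40, 5), c(45, 4, 1),
                c(10, 0, 10), c(12, 25, 13), c(40, 9, 1))
  for (counts in cases)
    expect_equal(hweTest(counts, method = "exact")$p.value,
                 hweExactOracle(counts), tolerance = 1e-10)
})

test_that("case-control genotype test reproduces the published p-value", {
  t1 <- genotypeCaseControlTest(c(305, 112, 14), c(202, 92, 10))
  expect_equal(t1$df, 2)
  expect_equal(t1$p.value, 0.433, tolerance = 0.01)
  same <- genotypeCaseControlTest(c(50, 30, 20), c(50, 30, 20))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p.value, 1)
  expect_lt(genotypeCaseControlTest(c(100, 0, 0), c(0, 0, 100))$p.value, 1e-6)
  # df drops when a genotype class is absent everywhere
  expect_equal(genotypeCaseControlTest(c(60, 40, 0), c(50, 50, 0))$df, 1)
})

test_that("Pearson statistic matches brute-force expected counts on small tables", {
  set.seed(7)
  for (i in 1:30) {
    a <- rbinom(3, 5, 0.6) + c(1, 0, 0)
    b <- rbinom(3, 5, 0.5) + c(1, 0, 1)
    tab <- cbind(a, b)
    keep <- rowSums(tab) > 0
    tab <- tab[keep, , drop = FALSE]
    if (nrow(tab) < 2 || any(colSums(tab) == 0)) next
    exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- sum((tab - exp_counts)^2 / exp_counts)
    got <- genotypeCaseControlTest(a * keep, b * keep)
    expect_equal(got$statistic, stat, tolerance = 1e-10)
  }
})

test_that("contingency odds ratios reproduce the published instrument ORs", {
  or1 <- contingencyOR(112, 319, 92, 212)
  expect_equal(round(or1$or, 2), 0.81)
  expect_equal(round(or1$ci, 2), c(0.58, 1.12))
  or2 <- contingencyOR(190, 241, 143, 161)
  expect_equal(round(or2$or, 2), 0.89)
  expect_equal(round(or2$ci, 2), c(0.66, 1.19))
  expect_equal(contingencyOR(10, 10, 10, 10)$or, 1)
  expect_warning(z <- contingencyOR(0, 10, 5, 10), "continuity")
  expect_true(z$corrected)
})

test_that("odds ratio is reciprocal under swapping exposure labels", {
  set.seed(3)
  for (i in 1:20) {
    cells <- rpois(4, 30) + 1
    f <- contingencyOR(cells[1], cells[2], cells[3], cells[4])
    r <- contingencyOR(cells[2], cells[1], cells[4], cells[3])
    expect_equal(f$or * r$or, 1, tolerance = 1e-12)
  }
})

test_that("genetic risk score counts risk genotypes with missing handling", {
  g <- rbind(c(1, 1), c(0, 0), c(1, NA), c(2, 1))
  colnames(g) <- c("rs1", "rs2")
  grs <- buildGRS(g, c(rs1 = "het", rs2 = "het"))
  expect_identical(grs, c(2L, 0L, NA_integer_, 1L))
  # relaxed call-rate threshold rescales from observed instruments
  grs2 <- buildGRS(g, c(rs1 = "het", rs2 = "het"), minCallRate = 0.5)
  expect_identical(grs2[3], 2L)
  gJ <- matrix(1L, 1, 5, dimnames = list(NULL, paste0("r", 1:5)))
  expect_identical(buildGRS(gJ, setNames(rep("het", 5), paste0("r", 1:5))), 5L)
  expect_error(buildGRS(g, c(nope = "het")), "nope")
  expect_error(buildGRS(g, c(rs1 = "hets")), "homRef, het or homAlt")
})
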