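test_that("IV-free residuals are orthogonal to the risk score", {
  cfg <- plainConfig(seed = 71, nCases = 500, nControls = 800)
  coh <- simulateCohort(cfg)
  grs <- buildGRS(coh, setNames(rep("het", 4), sprintf("s%02d", 1:4)))
  res <- ivFreeExposure(coh, grs)
  expect_lt(abs(mean(res)), 1e-10)
  expect_lt(abs(cor(res, grs)), 1e-10)
  expect_lt(var(res), var(exposureValues(coh)))
  expect_error(ivFreeExposure(coh, rep(1, ncol(coh))), "constant GRS")
  # zero genetic effect: residuals reduce to centred exposure
  x <- exposureValues(coh)
  g0 <- rep(c(0L, 1L), length.out = length(x))
  fit <- lm(x ~ g0)
  expect_equal(as.numeric(ivFreeExposure(coh, g0)),
               unname(residuals(fit)), tolerance = 1e-10)
})

test_that("quantile stratification partitions evenly and stably", {
  s <- stratifyResiduals(rnorm(100), 5)
  expect_equal(as.integer(table(s)), rep(20L, 5))
  expect_equal(sum(table(s)), 100L)
  expect_error(stratifyResiduals(rep(1, 50), 5), "distinct")
  x <- sort(rnorm(40))
  s2 <- stratifyResiduals(x, 2)
  expect_true(all(s2[1:20] == 1L) && all(s2[21:40] == 2L))
  # NA values stay unassigned
  s3 <- stratifyResiduals(c(NA, rnorm(20)), 2)
  expect_true(is.na(s3[1]))
})

test_that("a single stratum reproduces the unstratified GRS ratio estimate", {
  cfg <- plainConfig(seed = 81, nCases = 700, nControls = 900)
  coh <- simulateCohort(cfg)
  grs <- buildGRS(coh, setNames(rep("het", 4), sprintf("s%02d", 1:4)))
  lace <- laceEstimates(coh, grs, rep(1L, ncol(coh)))
  bx <- lm(exposureValues(coh) ~ grs)
  by <- glm(caseStatus(coh) ~ grs, family = binomial())
  expect_equal(lace$lace[1], coef(by)[["grs"]] / coef(bx)[["grs"]],
               tolerance = 1e-10)
})

test_that("LACE estimates are flat under a linear causal mechanism", {
  snps <- data.frame(snp_id = sprintf("s%02d", 1:8), maf = 0.3, delta = -0.15,
                     geneticModel = "overdominant")
  cfg <- plainConfig(seed = 91, nCases = 12000, nControls = 18000,
                     snps = snps, causalShape = "linear", theta = 1,
                     baselineLogOdds = -0.5 - 1.9)
  coh <- simulateCohort(cfg)
  grs <- buildGRS(coh, setNames(rep("het", 8), snps$snp_id))
  strata <- stratifyResiduals(ivFreeExposure(coh, grs), 5)
  lace <- laceEstimates(coh, grs, strata)
  expect_true(all(lace$ok))
  expect_true(all(abs(lace$lace - 1) < 3.5 * lace$se_lace))
})

test_that("LACE estimates increase with exposure under a convex causal curve", {
  snps <- data.frame(snp_id = sprintf("s%02d", 1:8), maf = 0.3, delta = -0.15,
                     geneticModel = "overdominant")
  rho <- vapply(1:5, function(r) {
    cfg <- plainConfig(seed = 110 + r, nCases = 5000, nControls = 7000,
                       snps = snps, causalShape = "quadratic", theta = -1,
                       theta2 = 0.8, baselineLogOdds = -0.4)
    coh <- simulateCohort(cfg)
    grs <- buildGRS(coh, setNames(rep("het", 8), snps$snp_id))
    strata <- stratifyResiduals(ivFreeExposure(coh, grs), 5)
    lace <- laceEstimates(coh, grs, strata)
    cor(lace$lace, lace$x_mean, method = "spearman")
  }, numeric(1))
  expect_true(all(rho > 0))
})

test_that("quadratic test: zero slope for identical LACEs, closed-form WLS", {
  flat <- strataTable(lace = rep(1.4, 5), se = rep(0.5, 5))
  qt <- quadraticTest(flat)
  expect_lt(abs(qt$slope), 1e-10)
  expect_error(quadraticTest(flat[1:2, ]), "at least 3")
  tilted <- strataTable(lace = c(1, 2, 3), se = c(0.5, 0.4, 0.3))
  w <- 1 / tilted$se_lace^2
  fitw <- lm(lace ~ x_mean, data = tilted, weights = w)
  expect_equal(quadraticTest(tilted)$slope, unname(coef(fitw)[2]),
               tolerance = 1e-10)
})

test_that("Cochran's Q matches closed-form arithmetic", {
  two <- strataTable(lace = c(0, 2), se = c(0.5, 0.5))
  q <- cochranQTest(two)
  expect_equal(q$Q, 8, tolerance = 1e-12)
  expect_equal(q$df, 1)
  expect_equal(q$p.value, pchisq(8, 1, lower.tail = FALSE), tolerance = 1e-12)
  same <- strataTable(lace = rep(0.7, 4), se = rep(0.3, 4))
  qs <- cochranQTest(same)
  expect_equal(qs$Q, 0, tolerance = 1e-12)
  expect_equal(qs$p.value, 1)
  expect_error(cochranQTest(same[1, ]), "at least 2")
})

test_that("fractional polynomial test identifies the generating power", {
  flat <- strataTable(lace = rep(2, 5), se = rep(0.2, 5),
                      x_mean = c(1.2, 1.5, 1.9, 2.3, 2.8))
  fp <- fracpolyTest(flat)
  expect_equal(fp$best_power, 1)
  expect_equal(fp$statistic, 0, tolerance = 1e-12)
  expect_equal(fp$p.value, 1)
  # LACE proportional to 1/x is the signature of a logarithmic causal curve
  x <- c(1.2, 1.5, 1.9, 2.3, 2.8)
  set.seed(10)
  log1 <- strataTable(lace = 2 / x + rnorm(5, 0, 1e-4), se = rep(0.05, 5),
                      x_mean = x)
  expect_equal(fracpolyTest(log1)$best_power, 0)
  expect_error(fracpolyTest(flat, powers = c(0, 2)), "must contain 1")
})

test_that("piecewise curve integrates a constant slope to a straight line", {
  x <- c(1.2, 1.5, 1.9, 2.3, 2.8)
  flat <- strataTable(lace = rep(0.7, 5), se = rep(0.2, 5), x_mean = x)
  cv <- piecewiseCurve(flat, reference = 1.9)
  expect_equal(cv$effect, 0.7 * (cv$x - 1.9), tolerance = 1e-10)
  expect_error(piecewiseCurve(flat, reference = 99), "reference")
  # continuity at stratum boundaries
  vary <- strataTable(lace = c(-1, 0.5, 2, 1, -0.5), se = rep(0.2, 5),
                      x_mean = x)
  cv2 <- piecewiseCurve(vary, reference = 1.9, n = 2001)
  expect_true(all(abs(diff(cv2$effect)) <
                    2.5 * max(abs(vary$lace)) * diff(cv2$x[1:2])))
})

test_that("fractional polynomial curve uses the correct antiderivative", {
  for (p in fracpolyPowers()) {
    numer <- integrate(function(v) v^(p - 1), 1, 3, rel.tol = 1e-10)$value
    G <- function(v) if (p == 0) log(v) else v^p / p
    expect_lt(abs(numer - (G(3) - G(1))), 1e-6)
  }
  x <- c(1.2, 1.5, 1.9, 2.3, 2.8)
  flat <- strataTable(lace = rep(0.7, 5), se = rep(0.2, 5), x_mean = x)
  cv <- fracpolyCurve(flat, power = 1, reference = 1.9)
  slope <- diff(cv$effect) / diff(cv$x)
  expect_equal(slope, rep(slope[1], length(slope)), tolerance = 1e-8)
  zero <- strataTable(lace = rep(0, 5), se = rep(0.2, 5), x_mean = x)
  cz <- fracpolyCurve(zero, power = 2, reference = 1.9)
  expect_true(all(abs(cz$effect) < 1e-10))
})

test_that("the assembled non-linear analysis returns the three tests", {
  snps <- data.frame(snp_id = sprintf("s%02d", 1:6), maf = 0.3, delta = -0.15,
                     geneticModel = "overdominant")
  cfg <- plainConfig(seed = 131, nCases = 1500, nControls = 2000, snps = snps)
  coh <- simulateCohort(cfg)
  grs <- buildGRS(coh, setNames(rep("het", 6), snps$snp_id))
  nl <- nonlinearMR(coh, grs, K = 5)
  tests <- nonlinearityTests(nl)
  expect_setequal(tests$test, c("quadratic", "cochran_q", "fracpoly"))
  expect_true(all(tests$p_value >= 0 & tests$p_value <= 1))
  expect_equal(nrow(laceTable(nl)), 5)
  expect_equal(sum(laceTable(nl)$n), ncol(coh))
  expect_named(causalCurves(nl), c("piecewise", "fracpoly"))
  # flagged strata: single-class outcome in a stratum is excluded with df drop
  expect_equal(tests$df[tests$test == "cochran_q"], 4)
})
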