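test_that("unadjusted logistic outcome association equals the contingency OR", {
  set.seed(8)
  n <- 500
  g <- cbind(rs1 = rbinom(n, 2, 0.3))
  y <- rbinom(n, 1, plogis(-0.3 + 0.5 * (g[, 1] == 1)))
  coh <- MRCohort(g, outcome = y, exposure = rnorm(n, 1.9))
  oa <- outcomeAssociation(coh, "rs1")
  het <- g[, 1] == 1
  or <- contingencyOR(sum(y == 1 & het), sum(y == 1 & !het),
                      sum(y == 0 & het), sum(y == 0 & !het))
  expect_equal(exp(oa$effect), or$or, tolerance = 1e-6)
})

test_that("IVW reduces to the ratio for one instrument and gains precision", {
  one <- data.frame(beta_x = 0.2, se_x = 0.02, beta_y = 0.1, se_y = 0.05)
  e1 <- ivwEstimate(one)
  expect_equal(mrTheta(e1), 0.5, tolerance = 1e-12)
  expect_equal(mrSE(e1), 0.05 / 0.2, tolerance = 1e-12)
  two <- data.frame(beta_x = c(0.2, 0.4), se_x = 0.02,
                    beta_y = c(0.1, 0.2), se_y = c(0.05, 0.06))
  e2 <- ivwEstimate(two)
  expect_equal(mrTheta(e2), 0.5, tolerance = 1e-12)
  expect_lt(mrSE(e2), min(0.05 / 0.2, 0.06 / 0.4))
  bad <- data.frame(beta_x = c(0.2, 0), se_x = 0.02,
                    beta_y = c(0.1, 0.2), se_y = 0.05)
  expect_message(e3 <- ivwEstimate(bad), "rejected")
  expect_equal(e3@nInstruments, 1L)
})

test_that("IVW equals the zero-intercept weighted least-squares slope", {
  for (r in 1:20) {
    s <- simulateSummary(J = 8, theta = 0.7, seed = 100 + r,
                         sx = 0.03, sy = 0.04)
    wls <- sum(s$beta_x * s$beta_y / s$se_y^2) / sum(s$beta_x^2 / s$se_y^2)
    expect_equal(mrTheta(ivwEstimate(s)), wls, tolerance = 1e-10)
  }
})

test_that("maximum likelihood estimator behaves at its known limits", {
  s <- simulateSummary(J = 6, theta = 0.5, seed = 42)
  # vanishing first-stage uncertainty: ML converges to IVW
  s0 <- s; s0$se_x <- 1e-6 * abs(s0$beta_x)
  expect_equal(mrTheta(mlEstimate(s0)), mrTheta(ivwEstimate(s0)),
               tolerance = 1e-4)
  one <- data.frame(beta_x = 0.25, se_x = 0.02, beta_y = -0.1, se_y = 0.05)
  expect_equal(mrTheta(mlEstimate(one)), -0.4, tolerance = 1e-6)
  # the optimum is at least as likely as the IVW point
  ml <- mlEstimate(s)
  nllAt <- function(theta)
    sum((s$beta_x - s$beta_x)^2 / (2 * s$se_x^2) +
          (s$beta_y - theta * s$beta_x)^2 / (2 * s$se_y^2))
  expect_lte(ml@diagnostics$negloglik, nllAt(mrTheta(ivwEstimate(s))) + 1e-9)
  expect_true(ml@diagnostics$converged)
})

test_that("maximum likelihood recovers the true effect across replicates", {
  est <- vapply(1:200, function(r)
    mrTheta(mlEstimate(simulateSummary(J = 10, theta = 0.5, seed = 2000 + r))),
    numeric(1))
  mcse <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.5), 3 * mcse)
})

test_that("mode-based estimator is exact on a point mass and robust to outliers", {
  pm <- data.frame(beta_x = c(0.2, 0.4, 0.1), se_x = 0.02,
                   beta_y = c(0.2, 0.4, 0.1) * 1.3, se_y = 0.05)
  e <- mbeEstimate(pm, seed = 1, nBoot = 50)
  expect_equal(mrTheta(e), 1.3, tolerance = 1e-9)
  expect_true(e@diagnostics$zeroSpread)
  set.seed(9)
  ratios <- c(rnorm(9, 1, 0.02), 10)
  out <- data.frame(beta_x = 1, se_x = 1e-4, beta_y = ratios, se_y = 0.3)
  eo <- mbeEstimate(out, seed = 2, nBoot = 50)
  expect_gt(mrTheta(eo), 0.8)
  expect_lt(mrTheta(eo), 1.2)
  expect_warning(mbeEstimate(pm[1:2, ], seed = 1, nBoot = 20), "degenerate")
})

test_that("mode matches a dense-grid argmax of the weighted kernel density", {
  s <- simulateSummary(J = 12, theta = 0.4, seed = 77, sy = 0.08)
  e <- mbeEstimate(s, seed = 3, nBoot = 10)
  r <- e@diagnostics$ratio
  h <- e@diagnostics$bandwidth
  w <- (1 / r$se^2) / sum(1 / r$se^2)
  grid <- seq(min(r$theta) - 3 * h, max(r$theta) + 3 * h, by = 1e-4)
  dens <- vapply(grid,
                 function(v) sum(w * dnorm(v, r$theta, h)), numeric(1))
  expect_lt(abs(mrTheta(e) - grid[which.max(dens)]), 1e-4 + 1e-9)
})

test_that("estimators are equivariant under a joint sign flip", {
  s <- simulateSummary(J = 6, theta = -0.6, seed = 55)
  f <- s; f$beta_x <- -f$beta_x; f$beta_y <- -f$beta_y
  expect_equal(mrTheta(ivwEstimate(f)), mrTheta(ivwEstimate(s)),
               tolerance = 1e-10)
  expect_equal(mrTheta(mlEstimate(f)), mrTheta(mlEstimate(s)),
               tolerance = 1e-6)
  expect_equal(mrTheta(mbeEstimate(f, seed = 4, nBoot = 20)),
               mrTheta(mbeEstimate(s, seed = 4, nBoot = 20)),
               tolerance = 1e-6)
})

test_that("OR per 10 percent decrease applies the ln(0.9) rescaling", {
  expect_equal(orPer10PctDecrease(0)$or, 1)
  expect_equal(orPer10PctDecrease(1)$or, 0.9)
  expect_equal(orPer10PctDecrease(-2.576)$or, 1.312, tolerance = 1e-3)
  z <- orPer10PctDecrease(-2, se = 0.5)
  expect_true(z$ci[1] < z$or && z$or < z$ci[2])
  # the alternative convention is the reciprocal
  expect_equal(orPer10PctDecrease(1, convention = "10/9")$or, 1 / 0.9,
               tolerance = 1e-12)
})

test_that("summary associations carry consistent stage results", {
  cfg <- plainConfig(seed = 61, nCases = 800, nControls = 1200)
  coh <- simulateCohort(cfg)
  s <- summaryAssociations(coh, c("s01", "s02"))
  expect_equal(nrow(s), 2)
  ea <- exposureAssociation(coh, "s01")
  oa <- outcomeAssociation(coh, "s01")
  expect_equal(s$beta_x[1], ea$effect)
  expect_equal(s$beta_y[1], oa$effect)
  expect_true(all(s$se_x > 0 & s$se_y > 0))
})
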