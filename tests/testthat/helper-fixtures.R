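# Small deterministic cohort: genotypes and exposure built by hand so that
# expected regression quantities are easy to reason about.
tinyCohort <- function(n = 60, seed = 11, delta = -0.2, maf = 0.4,
                       caseFrac = 0.5) {
  set.seed(seed)
  g <- cbind(rsA = rbinom(n, 2, maf), rsB = rbinom(n, 2, maf))
  x <- 1.9 + delta * (g[, "rsA"] == 1) + rnorm(n, 0, 0.25)
  y <- rbinom(n, 1, caseFrac)
  y[1] <- 1L; y[2] <- 0L # guarantee both classes
  MRCohort(g, outcome = y, exposure = x,
           covariates = data.frame(age = rnorm(n, 50, 10),
                                   sex = rbinom(n, 1, 0.5)))
}

# Covariate-free simulation config for estimator checks.
plainConfig <- function(seed, nCases = 400, nControls = 600,
                        snps = data.frame(snp_id = sprintf("s%02d", 1:4),
                                          maf = 0.3, delta = -0.15,
                                          geneticModel = "overdominant"),
                        causalShape = "null", theta = 0, theta2 = 0,
                        baselineLogOdds = -0.5, exposureSd = 0.3) {
  SimulationConfig(nCases = nCases, nControls = nControls, snps = snps,
                   exposureMean = 1.9, exposureSd = exposureSd,
                   causalShape = causalShape, theta = theta, theta2 = theta2,
                   baselineLogOdds = baselineLogOdds, seed = seed)
}

# Per-instrument summary statistics drawn around a true causal effect theta.
simulateSummary <- function(J, theta, seed, bx = 0.2, sx = 0.02, sy = 0.05) {
  set.seed(seed)
  betaX <- rnorm(J, bx, sx)
  betaY <- rnorm(J, theta * betaX, sy)
  data.frame(snp_id = sprintf("s%02d", seq_len(J)),
             beta_x = betaX, se_x = rep(sx, J),
             beta_y = betaY, se_y = rep(sy, J))
}

# Hand-made stratum table for the non-linearity tests.
strataTable <- function(lace, se, x_mean = seq_along(lace), n = 100) {
  K <- length(lace)
  data.frame(k = seq_len(K), n = rep(n, K), x_mean = x_mean,
             x_low = x_mean - 0.5, x_high = x_mean + 0.5,
             beta_x = rep(-0.1, K), se_x = rep(0.01, K),
             beta_y = lace * -0.1, se_y = se * 0.1,
             lace = lace, se_lace = se, ok = TRUE)
}

# Exact HWE oracle: full enumeration of heterozygote counts via binomial
# coefficients, P(h) = choose(n, aa) choose(n - aa, h) 2^h / choose(2n, nAlt).
hweExactOracle <- function(counts) {
  n <- sum(counts)
  nAlt <- counts[2] + 2 * counts[3]
  nA <- min(nAlt, 2 * n - nAlt)
  hets <- seq(nA %% 2, nA, by = 2)
  p <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    choose(n, aa) * choose(n - aa, h) * 2^h / choose(2 * n, nA)
  }, numeric(1))
  obs <- p[hets == counts[2]]
  sum(p[p <= obs * (1 + 1e-12)])
}
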