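test_that("gamma-Poisson pmf closed forms and normalization", {
  expect_equal(negbinPmf(0, 2, 2, 3), (2 / 5)^2)
  ## degenerate exposure: point mass at zero
  expect_equal(negbinPmf(0, 2, 2, 0), 1)
  expect_equal(negbinPmf(3, 2, 2, 0), 0)
  ## truncated-sum normalization over a parameter grid (wide support for the
  ## heavy-tailed low-shape case)
  expect_equal(sum(negbinPmf(0:500, 2, 2, 3)), 1, tolerance = 1e-10)
  for (par in list(c(0.5, 0.3, 1), c(2.19, 2.19, 5), c(0.22, 0.04, 2))) {
    s <- sum(negbinPmf(0:20000, par[1], par[2], par[3]))
    expect_equal(s, 1, tolerance = 1e-8)
  }
  ## the pmf depends on (beta, E) only through beta / E: joint scaling is exact
  expect_equal(negbinPmf(0:50, 1.5, 0.3, 4), negbinPmf(0:50, 1.5, 0.6, 8),
               tolerance = 1e-14)
  expect_error(negbinPmf(1, -1, 2, 3), class = "ddiInputError")
})

test_that("gamma-Poisson pmf agrees with the standard negative binomial", {
  k <- 0:50
  for (par in list(c(2, 2, 3), c(0.22, 0.04, 5), c(5, 1, 0.5))) {
    mine <- negbinPmf(k, par[1], par[2], par[3])
    ref <- dnbinom(k, size = par[1], prob = par[2] / (par[3] + par[2]))
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("gamma-Poisson pmf matches Monte-Carlo mixture frequencies", {
  set.seed(8)
  nmc <- 1e6
  lam <- rgamma(nmc, shape = 2, rate = 2)
  N <- rpois(nmc, 3 * lam)
  emp <- tabulate(N + 1, nbins = 21) / nmc
  theo <- negbinPmf(0:20, 2, 2, 3)
  mcse <- sqrt(theo * (1 - theo) / nmc)
  expect_true(all(abs(emp - theo) < 3 * pmax(mcse, 1e-6)))
})

test_that("conditional likelihood matches a scalar-loop oracle", {
  fix <- data.frame(N = c(1, 3, 10, 2, 40), E = c(0.5, 2, 8, 1.2, 20))
  p <- mixtureParams(2, 1, 0.2, 0.1)
  oracle <- oracleConditionalLogLik(2, 1, 0.2, 0.1, fix$N, fix$E)
  expect_equal(conditionalLogLik(p, fix$N, fix$E), oracle, tolerance = 1e-12)

  ## one-component limit: rho -> 0 leaves the zero-truncated background pmf
  tiny <- mixtureParams(2, 1, 0.2, 1e-14)
  single <- sum(log(dnbinom(fix$N, size = 2, prob = 2 / (fix$E + 2)) /
                    (1 - dnbinom(0, size = 2, prob = 2 / (fix$E + 2)))))
  expect_equal(conditionalLogLik(tiny, fix$N, fix$E), single, tolerance = 1e-6)

  expect_error(conditionalLogLik(p, c(0, 1), c(1, 1)), class = "ddiInputError")
})

test_that("conditional pmf normalizes at the reported parameter estimates", {
  p <- mixtureParams(2.19, 0.22, 0.04, 0.08)
  E <- 5
  k <- 1:20000
  logNum <- log(negbinPmf(k, 2.19, 2.19, E) + 0.08 * negbinPmf(k, 0.22, 0.04, E))
  den <- (1 - negbinPmf(0, 2.19, 2.19, E)) + 0.08 * (1 - negbinPmf(0, 0.22, 0.04, E))
  expect_equal(sum(exp(logNum)) / den, 1, tolerance = 1e-8)
  ## and the package likelihood of a unit fixture equals that construction
  expect_equal(conditionalLogLik(p, 7, E), logNum[7] - log(den), tolerance = 1e-12)
})

test_that("full likelihood handles the zero component", {
  p <- mixtureParams(2, 1, 0.2, 0.1, p1 = 0.3)
  fix <- data.frame(N = c(0, 2, 5), E = c(1, 3, 4))
  oracle <- 0
  for (i in 1:3) {
    p2 <- (1 - 0.3) / 1.1; p3 <- 0.1 * p2
    f2 <- dnbinom(fix$N[i], size = 2, prob = 2 / (fix$E[i] + 2))
    f3 <- dnbinom(fix$N[i], size = 1, prob = 0.2 / (fix$E[i] + 0.2))
    oracle <- oracle + log((fix$N[i] == 0) * 0.3 + p2 * f2 + p3 * f3)
  }
  expect_equal(fullLogLik(p, fix$N, fix$E), oracle, tolerance = 1e-12)

  ## all-zero data: likelihood increases monotonically in p1
  zeros <- rep(0, 20); E <- rep(2, 20)
  ll <- sapply(c(0.1, 0.5, 0.9), function(p1)
    fullLogLik(mixtureParams(2, 1, 0.2, 0.1, p1), zeros, E))
  expect_true(all(diff(ll) > 0))
  expect_error(fullLogLik(mixtureParams(2, 1, 0.2, 0.1), fix$N, fix$E),
               class = "ddiInputError")
})

test_that("conditional MLE maximizes the likelihood and pins the background", {
  dat <- simulateMixtureData(5000, alpha2 = 2, alpha3 = 1, beta3 = 0.2,
                             rho = 0.1, seed = 101)
  dat <- dat[dat$N > 0, ]
  fit <- fitConditional(dat$N, dat$E)
  p <- fittedParams(fit)
  ## the optimum dominates the generating parameters in likelihood
  expect_gte(fit@logLik,
             conditionalLogLik(mixtureParams(2, 1, 0.2, 0.1), dat$N, dat$E))
  ## the background dispersion is well identified at this sample size
  expect_lt(abs(p@alpha2 - 2) / 2, 0.15)
  ## the signal component sits above the background mean
  expect_gt(p@alpha3 / p@beta3, 1)
  ## fit is permutation-invariant
  set.seed(5)
  perm <- sample(nrow(dat))
  fit2 <- fitConditional(dat$N[perm], dat$E[perm])
  expect_equal(fittedParams(fit2)@alpha2, p@alpha2, tolerance = 1e-6)
  expect_error(fitConditional(c(0, 0, 0, 0, 1), rep(1, 5)), class = "ddiInputError")
  expect_error(fitConditional(c(1, 2), c(1, 1)), class = "ddiInputError")
})

test_that("full and conditional fits agree on shared parameters", {
  ## with a true zero mass of 0 and genuine zeros in the data, both routes are
  ## consistent for the shared parameters
  dat <- simulateMixtureData(4000, 2, 1, 0.2, 0.1, seed = 202,
                             eRange = c(0.2, 6))
  ff <- fittedParams(fitFull(dat$N, dat$E))
  pos <- dat[dat$N > 0, ]
  fc <- fittedParams(fitConditional(pos$N, pos$E))
  expect_lt(ff@p1, 0.05)
  expect_equal(fc@alpha2, ff@alpha2, tolerance = 0.1)
})

test_that("the fitted mixture is invariant to the exposure scale", {
  ## the relative-risk parameters describe N/E and must not depend on the
  ## magnitude of E when the latent relative risks are unchanged
  mk <- function(mult) {
    set.seed(303)
    E <- runif(5000, 1, 20) * mult
    sig <- runif(5000) < 0.1 / 1.1
    lam <- ifelse(sig, rgamma(5000, 1, rate = 0.2), rgamma(5000, 2, rate = 2))
    d <- data.frame(N = rpois(5000, lam * E), E = E)
    d[d$N > 0, ]
  }
  d1 <- mk(1); d2 <- mk(2)
  f1 <- fittedParams(fitConditional(d1$N, d1$E))
  f2 <- fittedParams(fitConditional(d2$N, d2$E))
  expect_equal(f2@alpha2, f1@alpha2, tolerance = 0.15)
})

test_that("adjusted FDR follows Bayes rule and its limits", {
  p <- mixtureParams(2.19, 0.22, 0.04, 0.08)
  f2 <- dnbinom(50, size = 2.19, prob = 2.19 / 7.19)
  f3 <- dnbinom(50, size = 0.22, prob = 0.04 / 5.04)
  expect_equal(adjustedFdr(p, 50, 5), f2 / (f2 + 0.08 * f3), tolerance = 1e-12)
  ## limits in the mass ratio
  expect_gt(adjustedFdr(mixtureParams(2.19, 0.22, 0.04, 1e-12), 50, 5), 1 - 1e-6)
  expect_lt(adjustedFdr(mixtureParams(2.19, 0.22, 0.04, 1e12), 50, 5), 1e-6)
  ## strictly decreasing in k when the signal gamma is stochastically larger
  ## with shape above 1 (a low-shape signal component piles mass near zero and
  ## can lift the FDR at the very first counts)
  vals <- adjustedFdr(mixtureParams(2, 2, 0.5, 0.1), 1:60, 5)
  expect_true(all(diff(vals) < 0))
  expect_error(adjustedFdr(p, 0, 5), class = "ddiInputError")
})

test_that("component moments follow the gamma closed forms", {
  m <- componentMoments(mixtureParams(2.19, 0.22, 0.04, 0.08))
  expect_equal(unname(m["mean2"]), 1)
  expect_equal(unname(m["sd2"]), 1 / sqrt(2.19))
  expect_equal(unname(m["mean3"]), 5.5)
  expect_equal(unname(m["sd3"]), sqrt(0.22) / 0.04)
  m2 <- componentMoments(mixtureParams(3, 4, 2, 0.1))
  expect_equal(unname(m2[c("mean3", "sd3")]), c(2, 1))
  ## the signal component must have mean above 1
  expect_error(mixtureParams(2, 1, 1, 0.1))
})
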