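test_that("PC basis reproduces an independent eigen decomposition", {
  set.seed(5)
  comed <- matrix(rbinom(50 * 20, 1, 0.3), 50, 20,
                  dimnames = list(NULL, paste0("drug", 1:20)))
  basis <- computePCBasis(comed, threshold = 0.70)
  ev <- eigen(cov(comed), symmetric = TRUE)$values
  frac <- ev / sum(ev)
  expect_equal(basis@varFrac, frac, tolerance = 1e-8)
  kOracle <- which(cumsum(frac) >= 0.70)[1]
  expect_equal(nComponents(basis), kOracle)
  ## K satisfies the minimality invariant
  expect_gte(sum(basis@varFrac[1:basis@K]), 0.70)
  if (basis@K > 1) expect_lt(sum(basis@varFrac[1:(basis@K - 1)]), 0.70)
})

test_that("PC basis handles degenerate spectra and excluded columns", {
  ## rank-1: one dominant component
  rank1 <- matrix(rep(c(0, 1), each = 10), 20, 5,
                  dimnames = list(NULL, paste0("d", 1:5)))
  expect_equal(nComponents(computePCBasis(rank1, 0.70)), 1L)
  ## equal column variances (identity matrix): eigenvalues tie, K = ceil(0.7 * 19)
  ident <- diag(20); colnames(ident) <- paste0("d", 1:20)
  expect_equal(nComponents(computePCBasis(ident, 0.70)), 14L)
  ## focal drugs are dropped before the decomposition
  set.seed(6)
  comed <- matrix(rbinom(200, 1, 0.4), 40, 5,
                  dimnames = list(NULL, paste0("d", 1:5)))
  b <- computePCBasis(comed, 0.9, exclude = c("d1", "d2"))
  expect_equal(nrow(b@rotation), 3L)
  expect_error(computePCBasis(comed * 0, 0.7), class = "ddiInputError")
})

test_that("propensity model agrees with glm and satisfies MLE calibration", {
  set.seed(21)
  n <- 2000
  sc <- matrix(rnorm(n * 3), n, 3)
  expo <- rbinom(n, 1, plogis(-1 + 0.8 * sc[, 1]))
  mod <- fitPS(expo, sc)
  ref <- glm(expo ~ sc, family = binomial())
  expect_equal(unname(mod@coefficients), unname(coef(ref)), tolerance = 1e-6)
  ## score-equation identity: mean PS equals empirical prevalence
  expect_equal(mean(mod@ps), mean(expo), tolerance = 1e-8)
  ## exposure independent of scores: PS collapses to the prevalence
  expoNull <- rbinom(n, 1, 0.25)
  nullMod <- fitPS(expoNull, sc)
  expect_lt(sd(nullMod@ps), 0.03)
  expect_equal(mean(nullMod@ps), mean(expoNull), tolerance = 1e-8)
  expect_error(fitPS(rep(1, n), sc), class = "ddiDegenerateError")
})

test_that("propensity model recovers a known logistic coefficient", {
  set.seed(22)
  n <- 5000
  pc <- rnorm(n)
  expo <- rbinom(n, 1, plogis(-1.5 + 0.6 * pc))
  mod <- fitPS(expo, matrix(pc))
  se <- sqrt(diag(vcov(glm(expo ~ pc, family = binomial()))))
  expect_lt(abs(mod@coefficients[2] - 0.6), 3 * se[2])
})

test_that("interaction model recovers generating coefficients", {
  set.seed(31)
  n <- 100000
  d1 <- rbinom(n, 1, 0.15); d2 <- rbinom(n, 1, 0.15)
  truth <- c(-5, 0.5, 0.5, 0.8)
  y <- rbinom(n, 1, plogis(truth[1] + truth[2] * d1 + truth[3] * d2 +
                           truth[4] * d1 * d2))
  fit <- fitInteraction(d1, d2, y)
  ref <- glm(y ~ d1 * d2, family = binomial())
  expect_equal(unname(fit@beta[1:4]), unname(coef(ref)), tolerance = 1e-5)
  se <- sqrt(diag(vcov(ref)))
  expect_true(all(abs(fit@beta[1:4] - truth) < 3 * se))
  expect_identical(unname(fit@beta[5:6]), c(0, 0))
  expect_error(fitInteraction(rep(0, n), rep(0, n), y),
               class = "ddiDegenerateError")
})

test_that("PS adjustment reduces interaction-coefficient bias under confounding", {
  set.seed(32)
  n <- 30000; b3 <- 0.5; b4 <- 2; b5 <- 2
  errAdj <- errUn <- numeric(10)
  for (r in 1:10) {
    ps1 <- rbeta(n, 1, 6); ps2 <- rbeta(n, 1, 6)
    d1 <- rbinom(n, 1, ps1); d2 <- rbinom(n, 1, ps2)
    y <- rbinom(n, 1, plogis(-4 + 0.3 * d1 + 0.3 * d2 + b3 * d1 * d2 +
                             b4 * ps1 + b5 * ps2))
    errAdj[r] <- fitInteraction(d1, d2, y, ps1, ps2)@beta["b3"] - b3
    errUn[r] <- fitInteraction(d1, d2, y)@beta["b3"] - b3
  }
  expect_lt(abs(mean(errAdj)), abs(mean(errUn)))
})

test_that("baseline expectations reduce correctly and respect bounds", {
  ## no drug effects: E is the baseline risk times the doubly-exposed count
  flat <- new("InteractionFit", beta = setNames(c(qlogis(0.2), 0, 0, 0, 0, 0),
                                                paste0("b", 0:5)),
              psAdjusted = FALSE, converged = TRUE, nObs = 100L)
  expect_equal(unname(expectedUnadjusted(flat, 100)), 20)

  hand <- new("InteractionFit", beta = setNames(c(-3, 1, 0.5, 2, 0, 0),
                                                paste0("b", 0:5)),
              psAdjusted = FALSE, converged = TRUE, nObs = 500L)
  expect_equal(unname(expectedUnadjusted(hand, 500)), 500 * plogis(-1.5))

  psFit <- new("InteractionFit", beta = setNames(c(-3, 1, 0.5, 2, 0.7, -0.4),
                                                 paste0("b", 0:5)),
               psAdjusted = TRUE, converged = TRUE, nObs = 500L)
  set.seed(41)
  ps1 <- rbeta(80, 1, 6); ps2 <- rbeta(80, 1, 6)
  ## element-wise loop oracle
  oracle <- 0
  for (i in 1:80) oracle <- oracle + plogis(-3 + 1 + 0.5 + 0.7 * ps1[i] - 0.4 * ps2[i])
  expect_equal(expectedAdjusted(psFit, ps1, ps2), oracle)
  expect_lte(expectedAdjusted(psFit, ps1, ps2), 80)

  ## constant PS: closed form
  expect_equal(expectedAdjusted(psFit, rep(0.2, 10), rep(0.3, 10)),
               10 * plogis(-3 + 1.5 + 0.7 * 0.2 - 0.4 * 0.3))

  ## with b4 = b5 = 0 the adjusted expectation equals the unadjusted one
  noPsEffect <- new("InteractionFit", beta = setNames(c(-3, 1, 0.5, 2, 0, 0),
                                                      paste0("b", 0:5)),
                    psAdjusted = TRUE, converged = TRUE, nObs = 500L)
  expect_equal(expectedAdjusted(noPsEffect, ps1, ps2),
               unname(expectedUnadjusted(noPsEffect, 80)))
  expect_error(expectedAdjusted(psFit, ps1, ps2[-1]), class = "ddiInputError")
  expect_error(expectedAdjusted(flat, ps1, ps2), class = "ddiInputError")
})

test_that("unbiasedness of N/E under the no-interaction null", {
  ## moderate-scale version of the null calibration: beta3 = 0, no confounding
  set.seed(51)
  n <- 50000
  ratios <- numeric(30)
  for (r in 1:30) {
    ps1 <- rbeta(n, 1, 6); ps2 <- rbeta(n, 1, 6)
    d1 <- rbinom(n, 1, ps1); d2 <- rbinom(n, 1, ps2)
    y <- rbinom(n, 1, plogis(-4.5 + 0.4 * d1 + 0.4 * d2))
    fit <- fitInteraction(d1, d2, y, ps1, ps2)
    both <- d1 == 1 & d2 == 1
    E <- expectedAdjusted(fit, ps1[both], ps2[both])
    ratios[r] <- sum(y[both]) / E
  }
  expect_lt(abs(mean(ratios) - 1), 0.05)
})
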