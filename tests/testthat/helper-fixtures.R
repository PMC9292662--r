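## Programmatic fixtures shared across test files.

## random report table: each report gets a random drug subset and ADE subset
randomReports <- function(n, drugs = LETTERS[1:6], ades = c("ade1", "ade2"),
                          pDrug = 0.3, pAde = 0.3, seed = 1) {
  set.seed(seed)
  data.frame(
    report_id = sprintf("r%04d", seq_len(n)),
    drugs = I(lapply(seq_len(n), function(i) drugs[runif(length(drugs)) < pDrug])),
    ades = I(lapply(seq_len(n), function(i) ades[runif(length(ades)) < pAde])))
}

## a contingency table with all cells positive
positiveTable <- function(seed = 1, lambda = 40) {
  set.seed(seed)
  v <- rpois(8, lambda) + 1
  ContingencyTable(v[1], v[2], v[3], v[4], v[5], v[6], v[7], v[8])
}

## synthetic (N, E) pairs drawn from the two-gamma mixture given N > 0 is not
## enforced; callers filter as needed
simulateMixtureData <- function(n, alpha2, alpha3, beta3, rho, seed,
                                eRange = c(1, 20)) {
  set.seed(seed)
  E <- runif(n, eRange[1], eRange[2])
  fromSignal <- runif(n) < rho / (1 + rho)
  lam <- ifelse(fromSignal,
                rgamma(n, shape = alpha3, rate = beta3),
                rgamma(n, shape = alpha2, rate = alpha2))
  N <- rpois(n, lam * E)
  data.frame(N = N, E = E)
}

## independent scalar evaluation of the conditional mixture likelihood,
## written against stats::dnbinom rather than the package's log-space path
oracleConditionalLogLik <- function(alpha2, alpha3, beta3, rho, N, E) {
  total <- 0
  for (i in seq_along(N)) {
    p2 <- alpha2 / (E[i] + alpha2)
    p3 <- beta3 / (E[i] + beta3)
    f2 <- dnbinom(N[i], size = alpha2, prob = p2)
    f3 <- dnbinom(N[i], size = alpha3, prob = p3)
    pos2 <- 1 - dnbinom(0, size = alpha2, prob = p2)
    pos3 <- 1 - dnbinom(0, size = alpha3, prob = p3)
    total <- total + log((f2 + rho * f3) / (pos2 + rho * pos3))
  }
  total
}
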