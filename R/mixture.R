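## Three-component mixture on the relative reporting ratio lambda across all
## drug-drug-ADE combinations, observed through N ~ Poisson(lambda * E).
## Marginalizing the gamma components gives negative binomial likelihoods;
## the point mass at lambda = 0 accounts for combinations that are never
## reported. Fitting uses the conditional (N > 0) likelihood by default, which
## does not change the local FDR.

## log of the gamma-Poisson (negative binomial) pmf
##   F(k; a, b, E) = Gamma(k+a) E^k b^a / (Gamma(a) k! (E+b)^(k+a))
#' @keywords internal
.logNegbin <- function(k, alpha, beta, E) {
  out <- lgamma(k + alpha) - lgamma(alpha) - lfactorial(k) +
    alpha * log(beta) + ifelse(k == 0, 0, k * log(E)) -
    (k + alpha) * log(E + beta)
  out[E == 0 & k > 0] <- -Inf
  out[E == 0 & k == 0] <- 0
  out
}

#' Gamma-Poisson (negative binomial) probability mass function
#'
#' Marginal distribution of \code{N ~ Poisson(lambda E)} with
#' \code{lambda ~ Gamma(shape = alpha, rate = beta)}:
#' \deqn{F(k; \alpha, \beta, E) = \frac{\Gamma(k+\alpha) E^k \beta^\alpha}
#'   {\Gamma(\alpha) k! (E+\beta)^{k+\alpha}}.}
#' Computed in log space. At \code{E = 0} the distribution is a point mass at
#' zero. Vectorized over all arguments.
#'
#' @param k non-negative integer counts.
#' @param alpha,beta gamma shape and rate, both positive.
#' @param E non-negative exposure (expected frequency scale).
#' @param log return log probabilities.
#' @return probabilities (or log probabilities).
#' @examples
#' negbinPmf(0, alpha = 2, beta = 2, E = 3)  # (beta / (E + beta))^alpha
#' @export
negbinPmf <- function(k, alpha, beta, E, log = FALSE) {
  if (any(alpha <= 0) || any(beta <= 0))
    .stopCondition("ddiInputError", "alpha and beta must be positive")
  if (any(E < 0)) .stopCondition("ddiInputError", "E must be non-negative")
  if (any(k < 0) || any(k != round(k)))
    .stopCondition("ddiInputError", "k must be non-negative integers")
  lp <- .logNegbin(k, alpha, beta, E)
  if (log) lp else exp(lp)
}

## log P(N > 0; alpha, beta, E) = log(1 - (beta/(E+beta))^alpha)
#' @keywords internal
.logPpos <- function(alpha, beta, E) {
  log(-expm1(alpha * (log(beta) - log(E + beta))))
}

#' Conditional log-likelihood of the two-gamma mixture given N > 0
#'
#' For combinations with positive observed frequency the zero component drops
#' out and the likelihood of each \code{(N, E)} datum is
#' \deqn{P(N = k \mid N > 0) = \frac{F(k; \alpha_2, \alpha_2, E) +
#'   \rho F(k; \alpha_3, \beta_3, E)}{P(N > 0; \alpha_2, \alpha_2, E) +
#'   \rho P(N > 0; \alpha_3, \beta_3, E)}}
#' with \code{rho = P3/P2}. Computed in log space throughout.
#'
#' @param params a \linkS4class{MixtureParams}.
#' @param N positive observed frequencies.
#' @param E positive expected frequencies.
#' @return the summed log-likelihood.
#' @export
conditionalLogLik <- function(params, N, E) {
  stopifnot(methods::is(params, "MixtureParams"))
  if (any(N <= 0)) .stopCondition("ddiInputError", "all N must be positive")
  if (any(E <= 0)) .stopCondition("ddiInputError", "all E must be positive")
  a2 <- params@alpha2; a3 <- params@alpha3; b3 <- params@beta3; rho <- params@rho
  num <- .logsumexp2(.logNegbin(N, a2, a2, E),
                     log(rho) + .logNegbin(N, a3, b3, E))
  den <- .logsumexp2(.logPpos(a2, a2, E), log(rho) + .logPpos(a3, b3, E))
  terms <- num - den
  if (any(!is.finite(terms))) {
    i <- which(!is.finite(terms))[1L]
    .stopCondition("ddiNumericalError",
      sprintf("non-finite likelihood term at datum %d (N=%g, E=%g)", i, N[i], E[i]))
  }
  sum(terms)
}

#' Full (zero-inflated) log-likelihood over all combinations
#'
#' The observed frequency of every combination, including \code{N = 0}, follows
#' \deqn{P(N) = P_1 I(N = 0) + P_2 F(N; \alpha_2, \alpha_2, E) +
#'   P_3 F(N; \alpha_3, \beta_3, E)}
#' with \code{P2 = (1 - p1) / (1 + rho)} and \code{P3 = rho P2}.
#'
#' @param params a \linkS4class{MixtureParams} with \code{p1} set.
#' @param N non-negative observed frequencies.
#' @param E positive expected frequencies.
#' @return the summed log-likelihood.
#' @export
fullLogLik <- function(params, N, E) {
  stopifnot(methods::is(params, "MixtureParams"))
  if (is.na(params@p1))
    .stopCondition("ddiInputError", "full likelihood requires p1")
  if (any(N < 0)) .stopCondition("ddiInputError", "N must be non-negative")
  if (any(E <= 0)) .stopCondition("ddiInputError", "all E must be positive")
  a2 <- params@alpha2; a3 <- params@alpha3; b3 <- params@beta3
  rho <- params@rho; p1 <- params@p1
  p2 <- (1 - p1) / (1 + rho)
  lmix <- .logsumexp2(log(p2) + .logNegbin(N, a2, a2, E),
                      log(p2 * rho) + .logNegbin(N, a3, b3, E))
  lzero <- ifelse(N == 0 & p1 > 0, log(p1), -Inf)
  terms <- .logsumexp2(lzero, lmix)
  if (any(!is.finite(terms))) {
    i <- which(!is.finite(terms))[1L]
    .stopCondition("ddiNumericalError",
      sprintf("non-finite likelihood term at datum %d (N=%g, E=%g)", i, N[i], E[i]))
  }
  sum(terms)
}

## deterministic start list: fixed spread plus a moment-based start computed
## from the observed N/E ratios
#' @keywords internal
.mixtureStarts <- function(N, E) {
  lam <- N / E
  rho0 <- min(max(mean(lam > 2), 1 / length(N)), 10)
  mu3 <- mean(lam[lam > 2])
  if (!is.finite(mu3) || mu3 <= 1.2) mu3 <- 3
  a30 <- 2
  b30 <- a30 / mu3
  starts <- list(
    moment = c(log(2), log(b30), log(a30 - b30), log(rho0)),
    mid    = c(log(2), log(0.2), log(0.8), log(0.1)),
    flat   = c(log(1), log(0.05), log(0.2), log(0.05)),
    tight  = c(log(5), log(0.5), log(2), log(0.3)),
    wide   = c(log(0.5), log(0.02), log(0.1), log(0.01)))
  starts
}

#' @keywords internal
.thetaToParams <- function(theta, p1 = NA_real_) {
  b3 <- exp(theta[2L])
  mixtureParams(exp(theta[1L]), b3 + exp(theta[3L]), b3, exp(theta[4L]), p1)
}

#' Conditional maximum-likelihood fit of the mixture
#'
#' Maximizes \code{\link{conditionalLogLik}} over
#' \code{(alpha2, alpha3, beta3, rho)} with \code{stats::nlminb} (a Newton-like
#' quasi-Newton optimizer). The constraints \code{alpha2 > 0},
#' \code{alpha3 > beta3 > 0}, \code{rho > 0} are enforced smoothly by
#' optimizing \code{(log alpha2, log beta3, log(alpha3 - beta3), log rho)}.
#' Five deterministic starting points are tried (one moment-based); the best
#' likelihood wins, so the fit is deterministic given the data.
#'
#' @param N positive observed frequencies (at least 4 data points).
#' @param E positive expected frequencies.
#' @return a \linkS4class{MixtureFit}.
#' @export
fitConditional <- function(N, E) {
  keep <- is.finite(N) & is.finite(E) & E > 0
  N <- N[keep]; E <- E[keep]
  if (any(N <= 0))
    .stopCondition("ddiInputError",
      "conditional fit requires N > 0 for every combination")
  if (length(N) < 4L)
    .stopCondition("ddiInputError",
      "need at least 4 combinations with N > 0 (parameter count)")
  obj <- function(theta) {
    p <- tryCatch(.thetaToParams(theta), error = function(e) NULL)
    if (is.null(p)) return(1e10)
    v <- tryCatch(-conditionalLogLik(p, N, E), error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }
  .runMultistart(obj, .mixtureStarts(N, E), length(N), p1 = NA_real_)
}

#' Full (zero-inflated) maximum-likelihood fit of the mixture
#'
#' Maximizes \code{\link{fullLogLik}} over the four mixture parameters and the
#' zero-component mass \code{p1} (logit-transformed). Combinations with
#' \code{N = 0} are informative here, unlike in \code{\link{fitConditional}}.
#'
#' @param N non-negative observed frequencies.
#' @param E positive expected frequencies.
#' @return a \linkS4class{MixtureFit} whose params carry \code{p1}.
#' @export
fitFull <- function(N, E) {
  keep <- is.finite(N) & is.finite(E) & E > 0
  N <- N[keep]; E <- E[keep]
  if (length(N) < 5L)
    .stopCondition("ddiInputError", "need at least 5 combinations (parameter count)")
  p10 <- min(max(mean(N == 0), 1e-4), 0.99)
  starts <- lapply(.mixtureStarts(pmax(N, 1), E),
                   function(s) c(s, stats::qlogis(p10)))
  obj <- function(theta) {
    p <- tryCatch(.thetaToParams(theta[1:4], stats::plogis(theta[5L])),
                  error = function(e) NULL)
    if (is.null(p)) return(1e10)
    v <- tryCatch(-fullLogLik(p, N, E), error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }
  .runMultistart(obj, starts, length(N), p1 = NULL)
}

#' @keywords internal
.runMultistart <- function(obj, starts, nUsed, p1) {
  best <- NULL; bestName <- NA_character_
  for (nm in names(starts)) {
    f <- tryCatch(
      stats::nlminb(starts[[nm]], obj,
                    control = list(rel.tol = 1e-10, iter.max = 500L)),
      error = function(e) NULL)
    if (!is.null(f) && is.finite(f$objective) &&
        (is.null(best) || f$objective < best$objective)) {
      best <- f; bestName <- nm
    }
  }
  if (is.null(best))
    .stopCondition("ddiConvergenceError", "all mixture optimizations failed")
  theta <- best$par
  params <- if (is.null(p1)) .thetaToParams(theta[1:4], stats::plogis(theta[5L]))
            else .thetaToParams(theta, p1)
  methods::new("MixtureFit", params = params, logLik = -best$objective,
               convergence = list(code = best$convergence,
                                  message = best$message, start = bestName,
                                  iterations = best$iterations),
               nUsed = as.integer(nUsed))
}

#' @describeIn fittedParams parameters of a mixture fit
#' @export
setMethod("fittedParams", "MixtureFit", function(object) object@params)

#' @describeIn componentMoments from raw parameters
#' @export
setMethod("componentMoments", "MixtureParams", function(object) {
  c(mean2 = 1,
    sd2 = 1 / sqrt(object@alpha2),
    mean3 = object@alpha3 / object@beta3,
    sd3 = sqrt(object@alpha3) / object@beta3)
})

#' @describeIn componentMoments from a fit
#' @export
setMethod("componentMoments", "MixtureFit",
          function(object) componentMoments(object@params))

#' @describeIn adjustedFdr from raw parameters
#' @export
setMethod("adjustedFdr", "MixtureParams", function(object, k, E) {
  if (any(k <= 0))
    .stopCondition("ddiInputError", "adjusted FDR is defined for k > 0 only")
  if (any(E <= 0)) .stopCondition("ddiInputError", "E must be positive")
  f2 <- .logNegbin(k, object@alpha2, object@alpha2, E)
  f3 <- log(object@rho) + .logNegbin(k, object@alpha3, object@beta3, E)
  1 / (1 + exp(f3 - f2))
})

#' @describeIn adjustedFdr from a fit
#' @export
setMethod("adjustedFdr", "MixtureFit",
          function(object, k, E) adjustedFdr(object@params, k, E))

setMethod("show", "MixtureParams", function(object) {
  cat(sprintf("MixtureParams: alpha2 = %.4g, alpha3 = %.4g, beta3 = %.4g, rho = %.4g",
              object@alpha2, object@alpha3, object@beta3, object@rho))
  if (!is.na(object@p1)) cat(sprintf(", p1 = %.4g", object@p1))
  cat("\n")
  m <- componentMoments(object)
  cat(sprintf("  background: mean 1, SD %.3f; signal: mean %.3f, SD %.3f\n",
              m["sd2"], m["mean3"], m["sd3"]))
})

setMethod("show", "MixtureFit", function(object) {
  cat(sprintf("MixtureFit on %d combinations, logLik %.3f (start '%s', code %d)\n",
              object@nUsed, object@logLik, object@convergence$start,
              object@convergence$code))
  methods::show(object@params)
})

#' Flat key-value summary of a mixture fit
#'
#' @param fit a \linkS4class{MixtureFit}.
#' @return named character vector (alpha2, alpha3, beta3, rho, loglik, n_used).
#' @export
mixtureSummary <- function(fit) {
  p <- fit@params
  c(alpha2 = format(p@alpha2), alpha3 = format(p@alpha3),
    beta3 = format(p@beta3), rho = format(p@rho),
    loglik = format(fit@logLik), n_used = format(fit@nUsed))
}
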