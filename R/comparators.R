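## Omega shrinkage statistic and proportional reporting ratios (PRR).
##
## Omega compares the observed frequency N = g of a drug-drug-ADE combination
## with an expected frequency under an additive odds baseline, shrunk through a
## Gamma(alpha, alpha) prior on the relative reporting ratio: the posterior is
## Gamma(N + alpha, E + alpha) and Omega = log2 of its mean; Omega025 is the
## log2 lower 95% credibility bound, the quantity used for signal generation.

#' Expected frequency under the additive odds baseline
#'
#' With odds \code{O_xy = r_xy / (1 - r_xy)} and the restrictions
#' \code{O10 <- max(O10, O00)}, \code{O01 <- max(O01, O00)} (so that a single
#' drug's ADE risk is never taken below the background risk), the expected
#' number of ADE reports among the \code{g + h} doubly-exposed reports is
#' \deqn{E = (1 - 1 / (O10 + O01 - O00 + 1)) (g + h).}
#'
#' @param ct a \linkS4class{ContingencyTable}; all four exposure margins must be
#'   non-empty and the three baseline rates strictly below 1.
#' @return expected frequency in [0, g + h].
#' @export
omegaExpected <- function(ct) {
  cts <- counts(ct)
  r <- reportingRates(ct)
  .omegaExpectedCells(r["r00"], r["r10"], r["r01"], cts["g"] + cts["h"])
}

## vectorized core; returns NA on undefined rates when strict = FALSE
#' @keywords internal
.omegaExpectedCells <- function(r00, r10, r01, nBoth, strict = TRUE) {
  bad <- is.na(r00) | is.na(r10) | is.na(r01) | is.na(nBoth) | nBoth <= 0 |
    r00 >= 1 | r10 >= 1 | r01 >= 1
  if (strict && any(bad))
    .stopCondition("ddiUndefinedRateError",
      "additive baseline needs all exposure margins non-empty and rates below 1")
  o00 <- r00 / (1 - r00)
  o10 <- pmax(r10 / (1 - r10), o00)
  o01 <- pmax(r01 / (1 - r01), o00)
  E <- (1 - 1 / (o10 + o01 - o00 + 1)) * nBoth
  E[bad] <- NA_real_
  unname(E)
}

#' Omega shrinkage statistic and credibility lower bound
#'
#' \code{omega = log2((N + alpha) / (E + alpha))}; \code{omega025} is the log2
#' of the exact 2.5\% quantile of the Gamma(N + alpha, rate = E + alpha)
#' posterior of the relative reporting ratio. A positive \code{omega025} flags
#' a DDI signal. Vectorized over \code{N} and \code{E}.
#'
#' @param N observed report frequencies (non-negative).
#' @param E expected report frequencies (non-negative).
#' @param alpha shrinkage prior parameter, positive; default 0.5.
#' @return data.frame with columns \code{omega} and \code{omega025}.
#' @examples
#' omegaStats(N = 10, E = 2)  # omega = log2(10.5 / 2.5)
#' @export
omegaStats <- function(N, E, alpha = 0.5) {
  if (alpha <= 0)
    .stopCondition("ddiInputError", "alpha must be positive")
  if (any(E < 0, na.rm = TRUE))
    .stopCondition("ddiInputError", "E must be non-negative")
  omega <- log2((N + alpha) / (E + alpha))
  omega025 <- log2(stats::qgamma(0.025, shape = N + alpha, rate = E + alpha))
  data.frame(omega = omega, omega025 = omega025)
}

#' Score one contingency table with the Omega statistic
#'
#' @param ct a \linkS4class{ContingencyTable}.
#' @param alpha shrinkage prior parameter.
#' @return an \linkS4class{OmegaResult}.
#' @export
omegaScore <- function(ct, alpha = 0.5) {
  E <- omegaExpected(ct)
  N <- observedN(ct)
  st <- omegaStats(N, E, alpha)
  methods::new("OmegaResult", N = N, E = E, omega = st$omega,
               omega025 = st$omega025, alpha = alpha)
}

setMethod("show", "OmegaResult", function(object) {
  cat(sprintf(
    "OmegaResult: N = %g, E = %.4g, omega = %.4f, omega025 = %.4f (alpha = %g)\n",
    object@N, object@E, object@omega, object@omega025, object@alpha))
})

#' Proportional reporting ratios for a drug pair and ADE
#'
#' PRRs of each constituent drug and of the pair treated as a single "new
#' drug", with lower 95\% confidence bounds
#' \code{PRR025 = exp(log(PRR) - 1.96 SD)}:
#' \deqn{PRR_{D1D2} = \frac{g / (g + h)}{(a + c + e) / (a + b + c + d + e + f)}}
#' and analogously for the single drugs on the margins excluding the pair.
#' The interaction signal rule flags the pair when its lower bound exceeds both
#' single-drug lower bounds.
#'
#' Zero cells make a ratio or its SD degenerate; by default they raise an error
#' of class \code{ddiZeroCellError} naming the degenerate term. Setting
#' \code{continuity = TRUE} adds 0.5 to every cell first (a documented option,
#' not applied silently).
#'
#' @param ct a \linkS4class{ContingencyTable}.
#' @param continuity add 0.5 to all eight cells before computing.
#' @return a \linkS4class{PrrResult}.
#' @examples
#' ct <- ContingencyTable(a = 100, b = 900, c = 20, d = 80,
#'                        e = 30, f = 70, g = 10, h = 10)
#' prrScore(ct)  # pair PRR = 4
#' @export
prrScore <- function(ct, continuity = FALSE) {
  v <- counts(ct)
  if (continuity) v <- v + 0.5
  a <- v["a"]; b <- v["b"]; c <- v["c"]; d <- v["d"]
  e <- v["e"]; f <- v["f"]; g <- v["g"]; h <- v["h"]
  terms <- c("c+g" = c + g, "c+d+g+h" = c + d + g + h, "a+e" = a + e,
             "a+b+e+f" = a + b + e + f, "e+g" = e + g, "e+f+g+h" = e + f + g + h,
             "a+c" = a + c, "a+b+c+d" = a + b + c + d, "g" = g, "g+h" = g + h,
             "a+c+e" = a + c + e, "a+b+c+d+e+f" = a + b + c + d + e + f)
  zero <- names(terms)[terms == 0]
  if (length(zero))
    .stopCondition("ddiZeroCellError",
      paste0("degenerate zero term(s) in PRR: ", paste(zero, collapse = ", ")))
  prr <- c(
    d1 = unname(((c + g) / (c + d + g + h)) / ((a + e) / (a + b + e + f))),
    d2 = unname(((e + g) / (e + f + g + h)) / ((a + c) / (a + b + c + d))),
    d1d2 = unname((g / (g + h)) / ((a + c + e) / (a + b + c + d + e + f))))
  sd <- c(
    d1 = sqrt(1 / (c + g) - 1 / (c + d + g + h) + 1 / (a + e) - 1 / (a + b + e + f)),
    d2 = sqrt(1 / (e + g) - 1 / (e + f + g + h) + 1 / (a + c) - 1 / (a + b + c + d)),
    d1d2 = sqrt(1 / g - 1 / (g + h) + 1 / (a + c + e) - 1 / (a + b + c + d + e + f)))
  prr025 <- exp(log(prr) - 1.96 * unname(sd))
  methods::new("PrrResult", prr = prr, prr025 = prr025,
               isSignal = unname(prr025["d1d2"] > max(prr025["d1"], prr025["d2"])))
}

setMethod("show", "PrrResult", function(object) {
  cat("PrrResult\n")
  m <- rbind(PRR = object@prr, PRR025 = object@prr025)
  colnames(m) <- c("drug1", "drug2", "pair")
  print(round(m, 4))
  cat("interaction signal:", object@isSignal, "\n")
})
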