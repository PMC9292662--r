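## Report-level simulator for benchmarking DDI signal detection.
##
## Per report: exposure propensities PS1, PS2 ~ Beta(shape1, shape2) i.i.d.,
## exposures D ~ Bernoulli(PS), and ADE outcome
##   logit P(Y = 1) = b0 + b1 D1 + b2 D2 + b3 D1 D2 + b4 PS1 + b5 PS2.
## Nonzero b4/b5 make the propensity a common cause of exposure and outcome,
## inducing confounding. Labelled studies draw each pair's coefficients
## uniformly from design ranges: signals have b3 in [0.1, 1], negative
## controls b3 in [-1, -0.1].

## Coefficient bounds (lower, upper) for b0..b5 per design situation:
##  (a) both NPIRR and PIRR signals, no confounding;
##  (b) NPIRR-only signals (b1 in [0.1, 2], b2 in [-2, 0.1]), no confounding;
##  (c) as (a) plus confounding (signal b4, b5 in [-2, 1]; negative in [-1, 1]).
#' @keywords internal
.betaRanges <- function(situation) {
  base <- function(b1, b2, b3, b45) {
    m <- rbind(b0 = c(-6, -5), b1 = b1, b2 = b2, b3 = b3, b4 = b45, b5 = b45)
    colnames(m) <- c("lower", "upper")
    m
  }
  switch(situation,
    a = list(signal = base(c(-0.8, 0.8), c(-0.8, 0.8), c(0.1, 1), c(0, 0)),
             negative = base(c(-0.8, 0.8), c(-0.8, 0.8), c(-1, -0.1), c(0, 0))),
    b = list(signal = base(c(0.1, 2), c(-2, 0.1), c(0.1, 1), c(0, 0)),
             negative = base(c(-0.8, 0.8), c(-0.8, 0.8), c(-1, -0.1), c(0, 0))),
    c = list(signal = base(c(-0.8, 0.8), c(-0.8, 0.8), c(0.1, 1), c(-2, 1)),
             negative = base(c(-0.8, 0.8), c(-0.8, 0.8), c(-1, -0.1), c(-1, 1))),
    .stopCondition("ddiInputError", "situation must be one of a, b, c"))
}

#' Build a simulation configuration
#'
#' Defaults are the benchmark study conditions: 100000 reports per pair,
#' 10000 signal and 10000 negative-control pairs, exposure propensity
#' PS ~ Beta(1, 6) (mean exposure rate 1/7), and the situation-specific
#' coefficient ranges described in \code{\linkS4class{SimulationConfig}}.
#'
#' @param situation "a", "b" or "c".
#' @param nReports reports per pair.
#' @param nSignals,nNegatives labelled pair counts.
#' @param psShape Beta shape parameters of the propensity law.
#' @param seed master seed (integer).
#' @param betaRanges optional override of the coefficient bounds (list with
#'   \code{signal} and \code{negative} 6 x 2 matrices).
#' @return a \linkS4class{SimulationConfig}.
#' @examples
#' simConfig("a", nReports = 1000, nSignals = 5, nNegatives = 5, seed = 1)
#' @export
simConfig <- function(situation = c("a", "b", "c"), nReports = 100000L,
                      nSignals = 10000L, nNegatives = 10000L,
                      psShape = c(1, 6), seed = 1L, betaRanges = NULL) {
  situation <- match.arg(situation)
  if (is.null(betaRanges)) betaRanges <- .betaRanges(situation)
  methods::new("SimulationConfig", situation = situation,
               nReports = as.integer(nReports), nSignals = as.integer(nSignals),
               nNegatives = as.integer(nNegatives), psShape = as.numeric(psShape),
               seed = as.integer(seed), betaRanges = betaRanges)
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: situation %s, %d signals + %d negatives, %d reports/pair\n",
    object@situation, object@nSignals, object@nNegatives, object@nReports))
  cat(sprintf("  PS ~ Beta(%g, %g), seed %d\n",
              object@psShape[1], object@psShape[2], object@seed))
})

#' Draw one pair's true coefficients
#'
#' Each coefficient is drawn uniformly from its design interval for the given
#' label; degenerate intervals (e.g. b4 = b5 = 0 in situations a and b)
#' produce that constant exactly.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param label "signal" or "negative".
#' @return named numeric vector b0..b5.
#' @export
drawPairParams <- function(config, label = c("signal", "negative")) {
  label <- match.arg(label)
  m <- config@betaRanges[[label]]
  stats::setNames(stats::runif(6L, m[, 1L], m[, 2L]), paste0("b", 0:5))
}

## core per-report generator; uses the current RNG state
#' @keywords internal
.simulateReports <- function(betas, nReports, psShape) {
  ps1 <- stats::rbeta(nReports, psShape[1], psShape[2])
  ps2 <- stats::rbeta(nReports, psShape[1], psShape[2])
  d1 <- as.numeric(stats::runif(nReports) < ps1)
  d2 <- as.numeric(stats::runif(nReports) < ps2)
  eta <- betas[1L] + betas[2L] * d1 + betas[3L] * d2 + betas[4L] * d1 * d2 +
    betas[5L] * ps1 + betas[6L] * ps2
  y <- as.numeric(stats::runif(nReports) < stats::plogis(eta))
  list(ps1 = ps1, ps2 = ps2, d1 = d1, d2 = d2, y = y)
}

#' Simulate one drug-pair dataset
#'
#' @param betas named coefficient vector b0..b5.
#' @param nReports number of reports.
#' @param psShape Beta shape parameters of the propensity law.
#' @param seed optional seed for a bit-reproducible dataset.
#' @param label pair label carried through to the result.
#' @return a \linkS4class{SimulatedPair} with per-report data and the derived
#'   contingency table.
#' @export
simulatePair <- function(betas, nReports, psShape = c(1, 6), seed = NULL,
                         label = "signal") {
  if (!is.null(seed)) set.seed(seed)
  rep <- .simulateReports(betas, nReports, psShape)
  cells <- .tabulateExposure(rep$d1 == 1, rep$d2 == 1, rep$y == 1)
  methods::new("SimulatedPair",
    betas = stats::setNames(as.numeric(betas), paste0("b", 0:5)),
    label = label,
    reports = data.frame(ps1 = rep$ps1, ps2 = rep$ps2, d1 = rep$d1,
                         d2 = rep$d2, y = rep$y),
    table = do.call(ContingencyTable, as.list(cells)))
}

setMethod("show", "SimulatedPair", function(object) {
  cat(sprintf("SimulatedPair (%s), %d reports\n", object@label,
              nrow(object@reports)))
  print(round(object@betas, 3))
  print(counts(object@table))
})

## seed for pair i of a study; stream 1..3 encodes the situation so different
## situations never share a pair stream
#' @keywords internal
.pairSeed <- function(config, i) {
  stream <- match(config@situation, c("a", "b", "c"))
  .deriveSeed(config@seed, stream, i)
}

#' Simulate a labelled study of many drug pairs
#'
#' Pairs are generated independently with a counter-based per-pair seed
#' derived from the master seed, so pair \code{i} is identical no matter how
#' many pairs are requested (prefix stability) and identical configurations
#' reproduce bit-identical studies. Signals come first, then negatives.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param summarize optional function \code{f(pairRows, cells)} receiving the
#'   per-report list (ps1, ps2, d1, d2, y) and the named cell counts, returning
#'   a named numeric vector of extra per-pair columns. Used by the benchmark to
#'   score pairs without retaining report-level data.
#' @return a \linkS4class{SimulatedStudy} whose \code{pairs} slot has one row
#'   per pair: pairId, label, b0..b5, cells a..h, N, plus any summarizer
#'   columns.
#' @export
simulateStudy <- function(config, summarize = NULL) {
  nTot <- config@nSignals + config@nNegatives
  rows <- vector("list", nTot)
  for (i in seq_len(nTot)) {
    label <- if (i <= config@nSignals) "signal" else "negative"
    set.seed(.pairSeed(config, i))
    betas <- drawPairParams(config, label)
    rep <- .simulateReports(betas, config@nReports, config@psShape)
    cells <- .tabulateExposure(rep$d1 == 1, rep$d2 == 1, rep$y == 1)
    extra <- if (is.null(summarize)) numeric(0) else summarize(rep, cells)
    rows[[i]] <- c(betas, cells, N = unname(cells["g"]), extra)
  }
  pairs <- as.data.frame(do.call(rbind, rows))
  pairs <- cbind(
    data.frame(pairId = sprintf("pair%05d", seq_len(nTot)),
               label = rep(c("signal", "negative"),
                           c(config@nSignals, config@nNegatives))),
    pairs)
  methods::new("SimulatedStudy", pairs = pairs, config = config)
}

setMethod("show", "SimulatedStudy", function(object) {
  cat(sprintf("SimulatedStudy: situation %s, %d pairs (%d signal / %d negative)\n",
              object@config@situation, nrow(object@pairs),
              sum(object@pairs$label == "signal"),
              sum(object@pairs$label == "negative")))
})
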