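#' ContingencyTable: the eight counts of a drug1 x drug2 x ADE classification
#'
#' Every spontaneous report falls in exactly one of eight cells according to
#' whether it mentions drug 1, drug 2 and the adverse event. Cells are named
#' \code{a}..\code{h} following the usual 2x2x2 layout: \code{a}/\code{b} are
#' ADE-yes/ADE-no among reports with neither drug, \code{c}/\code{d} with drug 1
#' only, \code{e}/\code{f} with drug 2 only, and \code{g}/\code{h} with both
#' drugs. The observed report frequency of the combination is \code{N = g}.
#'
#' @slot counts named numeric vector of the eight non-negative cell counts.
#' @slot drug1,drug2,ade character labels for the combination (may be empty).
#' @export
setClass("ContingencyTable",
  representation(counts = "numeric", drug1 = "character",
                 drug2 = "character", ade = "character"),
  prototype(counts = stats::setNames(numeric(8), c("a", "b", "c", "d", "e", "f", "g", "h")),
            drug1 = NA_character_, drug2 = NA_character_, ade = NA_character_)
)

setValidity("ContingencyTable", function(object) {
  ct <- object@counts
  if (length(ct) != 8L || !identical(names(ct), c("a", "b", "c", "d", "e", "f", "g", "h")))
    return("counts must be a named vector a..h of length 8")
  if (any(!is.finite(ct)) || any(ct < 0))
    return("cell counts must be finite and non-negative")
  if (any(ct != round(ct)))
    return("cell counts must be whole numbers")
  TRUE
})

#' Construct a ContingencyTable from the eight cell counts
#'
#' @param a,b,c,d,e,f,g,h non-negative integer cell counts (see class docs).
#' @param drug1,drug2,ade optional labels; the two drug labels are stored in
#'   canonical (lexicographic) order because the table is symmetric in them.
#' @return a \linkS4class{ContingencyTable}.
#' @examples
#' ct <- ContingencyTable(a = 100, b = 900, c = 20, d = 80,
#'                        e = 30, f = 70, g = 10, h = 10)
#' reportingRates(ct)
#' @export
ContingencyTable <- function(a, b, c, d, e, f, g, h,
                             drug1 = NA_character_, drug2 = NA_character_,
                             ade = NA_character_) {
  if (!is.na(drug1) && !is.na(drug2) && drug2 < drug1) {
    tmp <- drug1; drug1 <- drug2; drug2 <- tmp
    ctmp <- c; c <- e; e <- ctmp
    dtmp <- d; d <- f; f <- dtmp
  }
  methods::new("ContingencyTable",
    counts = c(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
               d = as.numeric(d), e = as.numeric(e), f = as.numeric(f),
               g = as.numeric(g), h = as.numeric(h)),
    drug1 = drug1, drug2 = drug2, ade = ade)
}

#' OmegaResult: Omega shrinkage statistic for one combination
#'
#' @slot N observed report frequency (the \code{g} cell).
#' @slot E expected frequency under the additive-odds baseline.
#' @slot omega log2 shrinkage observed-to-expected ratio.
#' @slot omega025 log2 of the lower 95\% credibility bound of the relative
#'   reporting ratio; a positive value flags a DDI signal.
#' @slot alpha shrinkage prior parameter.
#' @export
setClass("OmegaResult",
  representation(N = "numeric", E = "numeric", omega = "numeric",
                 omega025 = "numeric", alpha = "numeric"))

setValidity("OmegaResult", function(object) {
  if (object@alpha <= 0) return("alpha must be positive")
  if (object@E < 0) return("E must be non-negative")
  if (is.finite(object@omega) && is.finite(object@omega025) &&
      object@omega025 >= object@omega)
    return("omega025 must be below omega for finite N, E")
  TRUE
})

#' PrrResult: proportional reporting ratios for a drug pair and ADE
#'
#' Holds the PRR of each constituent drug and of the pair treated as a single
#' "new drug", together with the lower 95\% confidence bounds and the
#' interaction signal rule (pair bound exceeding both single-drug bounds).
#'
#' @slot prr named vector (d1, d2, d1d2) of point estimates.
#' @slot prr025 named vector (d1, d2, d1d2) of lower 95\% CI bounds.
#' @slot isSignal logical; \code{TRUE} when
#'   \code{prr025["d1d2"] > max(prr025["d1"], prr025["d2"])}.
#' @export
setClass("PrrResult",
  representation(prr = "numeric", prr025 = "numeric", isSignal = "logical"))

#' PCBasis: principal components of a comedication indicator matrix
#'
#' @slot rotation loading matrix (drugs x components), all components kept.
#' @slot center column means used for centering.
#' @slot varFrac explained-variance fraction per component, non-increasing.
#' @slot K number of retained components at the variance threshold.
#' @slot threshold the cumulative explained-variance threshold used.
#' @export
setClass("PCBasis",
  representation(rotation = "matrix", center = "numeric", varFrac = "numeric",
                 K = "integer", threshold = "numeric"))

setValidity("PCBasis", function(object) {
  if (object@K < 1L || object@K > ncol(object@rotation))
    return("K out of range")
  if (is.unsorted(rev(object@varFrac + 1e-12)))
    return("explained-variance fractions must be non-increasing")
  if (object@threshold <= 0 || object@threshold > 1)
    return("threshold must lie in (0, 1]")
  TRUE
})

#' PSModel: logistic propensity-score model for one drug
#'
#' @slot coefficients intercept and per-component log-odds coefficients.
#' @slot ps per-report fitted propensity scores in (0, 1).
#' @slot converged logical fit diagnostic.
#' @export
setClass("PSModel",
  representation(coefficients = "numeric", ps = "numeric", converged = "logical"))

#' InteractionFit: logistic outcome model for one drug pair and ADE
#'
#' The model is \code{logit P(ADE) = b0 + b1 D1 + b2 D2 + b3 D1 D2}
#' optionally extended with propensity-score covariates
#' \code{+ b4 PS1 + b5 PS2}. When the PS terms are omitted, \code{b4} and
#' \code{b5} are identically zero.
#'
#' @slot beta named coefficient vector b0..b5.
#' @slot psAdjusted whether the PS covariates were part of the fit.
#' @slot converged logical fit diagnostic.
#' @slot nObs number of reports used.
#' @export
setClass("InteractionFit",
  representation(beta = "numeric", psAdjusted = "logical",
                 converged = "logical", nObs = "integer"))

setValidity("InteractionFit", function(object) {
  if (length(object@beta) != 6L ||
      !identical(names(object@beta), paste0("b", 0:5)))
    return("beta must be named b0..b5")
  if (!object@psAdjusted && any(object@beta[c("b4", "b5")] != 0))
    return("b4 and b5 must be zero when the fit is not PS-adjusted")
  TRUE
})

#' MixtureParams: parameters of the three-component relative-risk mixture
#'
#' The unobserved relative reporting ratio lambda of a combination is modelled
#' as a point mass at zero (mass \code{p1}, combinations that can never be
#' reported), a gamma component with shape = rate = \code{alpha2} (background,
#' mean exactly 1), and a gamma component with shape \code{alpha3} > rate
#' \code{beta3} (signals, mean above 1). \code{rho} is the mass ratio of the
#' signal to the background component (P3/P2).
#'
#' @slot alpha2 shared shape/rate of the background gamma, positive.
#' @slot alpha3,beta3 shape and rate of the signal gamma, \code{alpha3 > beta3 > 0}.
#' @slot rho P3/P2 mass ratio, positive.
#' @slot p1 zero-component mass in [0, 1); \code{NA} for the conditional model.
#' @export
setClass("MixtureParams",
  representation(alpha2 = "numeric", alpha3 = "numeric", beta3 = "numeric",
                 rho = "numeric", p1 = "numeric"),
  prototype(p1 = NA_real_))

setValidity("MixtureParams", function(object) {
  if (object@alpha2 <= 0) return("alpha2 must be positive")
  if (object@beta3 <= 0) return("beta3 must be positive")
  if (object@alpha3 <= object@beta3)
    return("alpha3 must exceed beta3 (signal component mean above 1)")
  if (object@rho <= 0) return("rho must be positive")
  if (!is.na(object@p1) && (object@p1 < 0 || object@p1 >= 1))
    return("p1 must lie in [0, 1)")
  TRUE
})

#' Construct a MixtureParams object
#'
#' @param alpha2 background gamma shape (= rate), positive.
#' @param alpha3,beta3 signal gamma shape and rate with \code{alpha3 > beta3}.
#' @param rho mass ratio P3/P2, positive.
#' @param p1 optional zero-component mass for the full (zero-inflated) model.
#' @return a \linkS4class{MixtureParams}.
#' @examples
#' mixtureParams(2.19, 0.22, 0.04, 0.08)
#' @export
mixtureParams <- function(alpha2, alpha3, beta3, rho, p1 = NA_real_) {
  methods::new("MixtureParams", alpha2 = as.numeric(alpha2),
               alpha3 = as.numeric(alpha3), beta3 = as.numeric(beta3),
               rho = as.numeric(rho), p1 = as.numeric(p1))
}

#' MixtureFit: fitted three-component mixture
#'
#' @slot params the maximum-likelihood \linkS4class{MixtureParams}.
#' @slot logLik log-likelihood at the optimum.
#' @slot convergence optimizer diagnostics (code, message, start used).
#' @slot nUsed number of combinations entering the fit.
#' @export
setClass("MixtureFit",
  representation(params = "MixtureParams", logLik = "numeric",
                 convergence = "list", nUsed = "integer"))

#' SimulationConfig: study design for the report-level simulator
#'
#' @slot situation one of "a", "b", "c" (see \code{\link{simConfig}}).
#' @slot nReports reports per simulated drug pair.
#' @slot nSignals,nNegatives numbers of labelled positive / negative pairs.
#' @slot psShape Beta(shape1, shape2) law of the per-report exposure propensity.
#' @slot seed integer master seed.
#' @slot betaRanges list with elements \code{signal} and \code{negative}, each a
#'   2-column matrix of lower/upper bounds for b0..b5.
#' @export
setClass("SimulationConfig",
  representation(situation = "character", nReports = "integer",
                 nSignals = "integer", nNegatives = "integer",
                 psShape = "numeric", seed = "integer", betaRanges = "list"))

setValidity("SimulationConfig", function(object) {
  if (!object@situation %in% c("a", "b", "c")) return("situation must be a, b or c")
  if (object@nReports < 1L) return("nReports must be positive")
  if (object@nSignals < 0L || object@nNegatives < 0L)
    return("pair counts must be non-negative")
  if (length(object@psShape) != 2L || any(object@psShape <= 0))
    return("psShape must be two positive Beta parameters")
  rng <- object@betaRanges
  if (!all(c("signal", "negative") %in% names(rng)))
    return("betaRanges must have signal and negative elements")
  for (nm in c("signal", "negative")) {
    m <- rng[[nm]]
    if (!is.matrix(m) || nrow(m) != 6L || ncol(m) != 2L)
      return("each beta range must be a 6 x 2 matrix of bounds")
    if (any(m[, 1] > m[, 2])) return("beta range lower bounds exceed upper bounds")
  }
  TRUE
})

#' SimulatedPair: one simulated drug-pair dataset
#'
#' @slot betas true generating coefficients b0..b5.
#' @slot label "signal" or "negative".
#' @slot reports data.frame with per-report ps1, ps2, d1, d2, y
#'   (may have zero rows when reports were not retained).
#' @slot table the derived \linkS4class{ContingencyTable}.
#' @export
setClass("SimulatedPair",
  representation(betas = "numeric", label = "character",
                 reports = "data.frame", table = "ContingencyTable"))

setValidity("SimulatedPair", function(object) {
  if (!object@label %in% c("signal", "negative"))
    return("label must be signal or negative")
  if (!identical(names(object@betas), paste0("b", 0:5)))
    return("betas must be named b0..b5")
  TRUE
})

#' SimulatedStudy: a labelled collection of simulated pairs
#'
#' @slot pairs data.frame with one row per pair: pairId, label, true betas
#'   b0..b5, cells a..h and N.
#' @slot config the generating \linkS4class{SimulationConfig}.
#' @export
setClass("SimulatedStudy",
  representation(pairs = "data.frame", config = "SimulationConfig"))
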