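#' Cell counts of a contingency table
#'
#' @param object a \linkS4class{ContingencyTable}.
#' @return named numeric vector a..h.
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))

#' Relative reporting rates of a contingency table
#'
#' Rates are \code{r00 = a/(a+b)}, \code{r10 = c/(c+d)}, \code{r01 = e/(e+f)},
#' \code{r11 = g/(g+h)}. A rate whose denominator is zero is returned as
#' \code{NA} (undefined), never as 0.
#'
#' @param object a \linkS4class{ContingencyTable}.
#' @return named numeric vector r00, r10, r01, r11 (with NA for undefined).
#' @export
setGeneric("reportingRates", function(object) standardGeneric("reportingRates"))

#' Observed report frequency N of a combination
#'
#' @param object a \linkS4class{ContingencyTable}.
#' @return the \code{g} cell count.
#' @export
setGeneric("observedN", function(object) standardGeneric("observedN"))

#' Classify the individual-drug risk pattern of a combination
#'
#' A combination is NPIRR (nonpositive individual drug relative ADE risk) when
#' at least one constituent drug's marginal reporting rate does not exceed the
#' background rate (\code{r10 - r00 <= 0} or \code{r01 - r00 <= 0}); it is PIRR
#' when both differences are strictly positive. Tables with an undefined
#' marginal rate are "undefined".
#'
#' @param object a \linkS4class{ContingencyTable}, or a data.frame with cell
#'   columns \code{a}..\code{f}.
#' @return factor with levels NPIRR, PIRR, undefined.
#' @export
setGeneric("classifyPattern", function(object) standardGeneric("classifyPattern"))

#' Mixture parameters of a fitted object
#'
#' @param object a \linkS4class{MixtureFit}.
#' @return the \linkS4class{MixtureParams}.
#' @export
setGeneric("fittedParams", function(object) standardGeneric("fittedParams"))

#' Means and standard deviations of the gamma mixture components
#'
#' For a gamma with shape \code{a} and rate \code{b} the mean is \code{a/b} and
#' the SD is \code{sqrt(a)/b}. The background component has shape = rate so its
#' mean is identically 1 and its SD is \code{1/sqrt(alpha2)}.
#'
#' @param object a \linkS4class{MixtureParams} or \linkS4class{MixtureFit}.
#' @return named vector (mean2, sd2, mean3, sd3).
#' @export
setGeneric("componentMoments", function(object) standardGeneric("componentMoments"))

#' Local false discovery rate of observed frequencies under a fitted mixture
#'
#' @param object a \linkS4class{MixtureParams} or \linkS4class{MixtureFit}.
#' @param k observed report frequencies, all positive integers.
#' @param E expected report frequencies, all positive.
#' @return posterior probabilities that each combination has background
#'   relative risk (values in (0, 1)).
#' @export
setGeneric("adjustedFdr", function(object, k, E) standardGeneric("adjustedFdr"))
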