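## Propensity-score construction and expected frequencies under the
## no-interaction (multiplicative odds) baseline.
##
## The propensity score of a drug is the probability of exposure given a
## report's comedication profile, modelled as a logistic regression on
## principal components of the binary comedication indicator matrix. The
## per-combination outcome model
##   logit P(ADE) = b0 + b1 D1 + b2 D2 + b3 D1 D2 (+ b4 PS1 + b5 PS2)
## yields expected frequencies for the doubly-exposed reports with the
## interaction term removed: unadjusted (closed form) or PS-adjusted
## (summing per-report predicted risks).

#' Principal components of a comedication indicator matrix
#'
#' Columns are centred but not scaled to unit variance (covariance PCA):
#' rare-drug columns genuinely carry less variance and scaling would inflate
#' them. The number of retained components K is the smallest count whose
#' cumulative explained-variance fraction reaches \code{threshold}. Loading
#' signs are fixed so each component's largest-magnitude loading is positive,
#' making the basis deterministic.
#'
#' @param comed binary reports x drugs indicator matrix.
#' @param threshold cumulative explained-variance fraction in (0, 1];
#'   default 0.70.
#' @param exclude optional drug identifiers (column names) to drop before the
#'   decomposition, e.g. the two focal drugs of a pair.
#' @return a \linkS4class{PCBasis}.
#' @export
computePCBasis <- function(comed, threshold = 0.70, exclude = NULL) {
  if (threshold <= 0 || threshold > 1)
    .stopCondition("ddiInputError", "threshold must lie in (0, 1]")
  if (!is.null(exclude))
    comed <- comed[, !(colnames(comed) %in% exclude), drop = FALSE]
  if (ncol(comed) == 0L || nrow(comed) == 0L)
    .stopCondition("ddiInputError", "comedication matrix is empty")
  if (all(apply(comed, 2, stats::var) == 0))
    .stopCondition("ddiInputError", "comedication matrix has zero variance")
  pc <- stats::prcomp(comed, center = TRUE, scale. = FALSE)
  varFrac <- pc$sdev^2 / sum(pc$sdev^2)
  rot <- pc$rotation
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  K <- which(cumsum(varFrac) >= threshold - 1e-12)[1L]
  methods::new("PCBasis", rotation = rot, center = pc$center,
               varFrac = varFrac, K = as.integer(K),
               threshold = threshold)
}

#' Per-report component scores under a PC basis
#'
#' @param basis a \linkS4class{PCBasis}.
#' @param comed binary indicator matrix with the same columns the basis was
#'   computed from.
#' @param k number of leading components; defaults to the basis' retained K.
#' @return numeric matrix of scores (reports x k).
#' @export
pcScores <- function(basis, comed, k = basis@K) {
  scale(comed, center = basis@center, scale = FALSE) %*%
    basis@rotation[, seq_len(k), drop = FALSE]
}

#' Number of components retained by a PC basis
#'
#' @param basis a \linkS4class{PCBasis}.
#' @return integer K.
#' @export
nComponents <- function(basis) basis@K

setMethod("show", "PCBasis", function(object) {
  cat(sprintf("PCBasis: %d components retained (threshold %.2f, cum. var %.3f)\n",
              object@K, object@threshold, sum(object@varFrac[seq_len(object@K)])))
})

#' Fit a propensity-score model for one drug
#'
#' Maximum-likelihood logistic regression of the binary exposure indicator on
#' principal-component scores: \code{logit P(Drug = 1) = a0 + sum_i a_i PC_i}.
#'
#' @param exposure binary (0/1) exposure vector; both classes must be present.
#' @param scores matrix of per-report PC scores.
#' @return a \linkS4class{PSModel} with per-report propensity scores.
#' @export
fitPS <- function(exposure, scores) {
  exposure <- as.numeric(exposure)
  if (length(unique(exposure)) < 2L)
    .stopCondition("ddiDegenerateError", "exposure must contain both classes")
  scores <- as.matrix(scores)
  X <- cbind(1, scores)
  fit <- .irlsLogistic(X, exposure)
  if (fit$singular)
    .stopCondition("ddiSeparationError",
      "propensity model is rank deficient or separated")
  ps <- stats::plogis(drop(X %*% fit$coefficients))
  methods::new("PSModel",
    coefficients = stats::setNames(fit$coefficients,
                                   c("a0", paste0("a", seq_len(ncol(scores))))),
    ps = ps, converged = fit$converged)
}

setMethod("show", "PSModel", function(object) {
  cat(sprintf("PSModel: %d coefficients, mean PS %.4f, converged: %s\n",
              length(object@coefficients), mean(object@ps), object@converged))
})

#' Fit the per-combination logistic outcome model
#'
#' Fits \code{logit P(ADE) = b0 + b1 D1 + b2 D2 + b3 D1 D2} and, when
#' propensity scores are supplied, the PS-adjusted extension with
#' \code{+ b4 PS1 + b5 PS2}. Rank-deficient designs (for instance no exposed
#' reports at all) raise an error of class \code{ddiDegenerateError};
#' non-convergence and quasi-separation are reported through the
#' \code{converged} flag so a pipeline can skip the combination.
#'
#' @param d1,d2 binary exposure vectors.
#' @param y binary ADE outcome vector; both classes must be present.
#' @param ps1,ps2 optional per-report propensity scores of the two drugs;
#'   supply both or neither.
#' @param ridge optional non-negative ridge penalty added to the normal
#'   equations as a quasi-separation guard; 0 (off) by default.
#' @return an \linkS4class{InteractionFit}.
#' @export
fitInteraction <- function(d1, d2, y, ps1 = NULL, ps2 = NULL, ridge = 0) {
  d1 <- as.numeric(d1); d2 <- as.numeric(d2); y <- as.numeric(y)
  psAdjusted <- !is.null(ps1) || !is.null(ps2)
  if (psAdjusted && (is.null(ps1) || is.null(ps2)))
    .stopCondition("ddiInputError", "supply both ps1 and ps2 or neither")
  if (length(unique(y)) < 2L)
    .stopCondition("ddiDegenerateError", "outcome must contain both classes")
  X <- if (psAdjusted) cbind(1, d1, d2, d1 * d2, ps1, ps2)
       else cbind(1, d1, d2, d1 * d2)
  if (qr(X)$rank < ncol(X))
    .stopCondition("ddiDegenerateError",
      "design matrix is rank deficient (degenerate exposure pattern)")
  fit <- .irlsLogistic(X, y, ridge = ridge)
  beta <- stats::setNames(numeric(6), paste0("b", 0:5))
  beta[seq_len(ncol(X))] <- fit$coefficients
  if (!psAdjusted) beta[c("b4", "b5")] <- 0
  methods::new("InteractionFit", beta = beta, psAdjusted = psAdjusted,
               converged = fit$converged && !fit$singular,
               nObs = length(y))
}

setMethod("show", "InteractionFit", function(object) {
  cat("InteractionFit", if (object@psAdjusted) "(PS-adjusted)" else "(unadjusted)",
      "on", object@nObs, "reports\n")
  print(round(object@beta, 4))
  if (!object@converged) cat("WARNING: fit did not converge\n")
})

#' Expected frequency under the multiplicative odds baseline, unadjusted
#'
#' Removing the interaction term, the no-DDI risk of the doubly-exposed
#' reports is \code{invlogit(b0 + b1 + b2)}, so
#' \code{E = invlogit(b0 + b1 + b2) * (g + h)}.
#'
#' @param fit a converged \linkS4class{InteractionFit}.
#' @param nExposedBoth number of doubly-exposed reports (g + h).
#' @return expected frequency in [0, g + h].
#' @export
expectedUnadjusted <- function(fit, nExposedBoth) {
  if (!fit@converged)
    .stopCondition("ddiConvergenceError", "interaction fit did not converge")
  b <- fit@beta
  .invlogit(b["b0"] + b["b1"] + b["b2"]) * nExposedBoth
}

#' Expected frequency under the multiplicative odds baseline, PS-adjusted
#'
#' Sums the no-interaction predicted risk over the doubly-exposed reports,
#' keeping each report's propensity-score contribution:
#' \code{E = sum_i invlogit(b0 + b1 + b2 + b4 PS1_i + b5 PS2_i)}. Reduces
#' exactly to \code{\link{expectedUnadjusted}} when \code{b4 = b5 = 0}.
#'
#' @param fit a converged, PS-adjusted \linkS4class{InteractionFit}.
#' @param ps1Exposed,ps2Exposed propensity scores of the g + h doubly-exposed
#'   reports (equal lengths).
#' @return expected frequency in [0, g + h].
#' @export
expectedAdjusted <- function(fit, ps1Exposed, ps2Exposed) {
  if (!fit@converged)
    .stopCondition("ddiConvergenceError", "interaction fit did not converge")
  if (!fit@psAdjusted)
    .stopCondition("ddiInputError", "fit does not include propensity-score terms")
  if (length(ps1Exposed) != length(ps2Exposed))
    .stopCondition("ddiInputError", "ps1Exposed and ps2Exposed lengths differ")
  b <- fit@beta
  sum(.invlogit(b["b0"] + b["b1"] + b["b2"] +
                b["b4"] * ps1Exposed + b["b5"] * ps2Exposed))
}
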