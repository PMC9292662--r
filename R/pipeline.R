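## Orchestration: scoring tables of combinations, the report-level scoring
## path, and the end-to-end simulation benchmark.

#' Score a table of contingency counts with Omega and PRR
#'
#' Adds to each combination row the observed frequency \code{N}, the additive
#' baseline expectation \code{E_additive}, \code{omega} / \code{omega025}, the
#' PRR triple with lower bounds and the PRR interaction signal flag.
#' Combinations whose counts make a statistic undefined get \code{NA} in the
#' affected columns (no silent continuity correction).
#'
#' @param df data.frame with columns \code{a}..\code{h} (e.g. from
#'   \code{\link{readContingency}} or \code{\link{tabulateCombinations}}).
#' @param alpha Omega shrinkage prior parameter.
#' @param continuity apply the 0.5 continuity correction in the PRR.
#' @return \code{df} with score columns appended.
#' @export
scoreContingency <- function(df, alpha = 0.5, continuity = FALSE) {
  for (col in letters[1:8]) if (is.null(df[[col]]))
    .stopCondition("ddiInputError", paste0("missing cell column ", col))
  r00 <- ifelse(df$a + df$b > 0, df$a / (df$a + df$b), NA_real_)
  r10 <- ifelse(df$c + df$d > 0, df$c / (df$c + df$d), NA_real_)
  r01 <- ifelse(df$e + df$f > 0, df$e / (df$e + df$f), NA_real_)
  df$N <- df$g
  df$E_additive <- .omegaExpectedCells(r00, r10, r01, df$g + df$h, strict = FALSE)
  om <- omegaStats(df$N, ifelse(is.na(df$E_additive), 0, df$E_additive), alpha)
  df$omega <- ifelse(is.na(df$E_additive), NA_real_, om$omega)
  df$omega025 <- ifelse(is.na(df$E_additive), NA_real_, om$omega025)
  prrCols <- t(vapply(seq_len(nrow(df)), function(i) {
    res <- tryCatch(
      prrScore(do.call(ContingencyTable, as.list(unlist(df[i, letters[1:8]]))),
               continuity = continuity),
      ddiZeroCellError = function(e) NULL)
    if (is.null(res)) rep(NA_real_, 7)
    else c(res@prr, res@prr025, as.numeric(res@isSignal))
  }, numeric(7)))
  colnames(prrCols) <- c("prr_d1", "prr_d2", "prr_d1d2",
                         "prr025_d1", "prr025_d2", "prr025_d1d2", "prr_signal")
  cbind(df, prrCols)
}

#' Score report-level data with the full PS-adjusted pipeline
#'
#' Enumerates drug pairs above the frequency threshold, tabulates each
#' combination, and computes Omega, PRR and the propensity-score-adjusted and
#' unadjusted expected frequencies. Propensity scores are fitted per focal
#' drug by logistic regression on principal components of the comedication
#' indicator matrix with the pair's own columns removed (a drug must not
#' predict its own exposure). Combinations whose fits fail or separate are
#' flagged, not imputed; when at least four converged combinations have
#' \code{N > 0} the conditional mixture is fitted and adjusted-FDR columns are
#' added.
#'
#' @param reports report data.frame (see \code{\link{readReports}}).
#' @param ades ADE terms to analyse.
#' @param minPairFreq pair co-occurrence threshold (strict); default 50.
#' @param threshold PC explained-variance threshold; default 0.70.
#' @param alpha Omega shrinkage prior.
#' @param psAdjust fit PS-adjusted expectations (otherwise only unadjusted).
#' @return list with \code{scores} (per-combination data.frame) and
#'   \code{mixture} (a \linkS4class{MixtureFit} or NULL).
#' @export
scoreReports <- function(reports, ades, minPairFreq = 50L, threshold = 0.70,
                         alpha = 0.5, psAdjust = TRUE) {
  scores <- tabulateCombinations(reports, ades, minPairFreq = minPairFreq)
  scores <- scoreContingency(scores, alpha = alpha)
  allDrugs <- sort(unique(unlist(reports$drugs)))
  comed <- vapply(allDrugs,
                  function(dr) vapply(reports$drugs, function(s) dr %in% s, logical(1)),
                  logical(nrow(reports))) + 0
  colnames(comed) <- allDrugs
  n <- nrow(scores)
  eAdj <- eUn <- rep(NA_real_, n)
  conv <- rep(FALSE, n)
  for (i in seq_len(n)) {
    dr1 <- scores$drug1[i]; dr2 <- scores$drug2[i]
    d1 <- comed[, dr1]; d2 <- comed[, dr2]
    y <- vapply(reports$ades, function(s) scores$ade[i] %in% s, logical(1)) + 0
    res <- tryCatch({
      if (psAdjust) {
        basis <- computePCBasis(comed, threshold = threshold,
                                exclude = c(dr1, dr2))
        sc <- pcScores(basis, comed[, setdiff(allDrugs, c(dr1, dr2)), drop = FALSE])
        ps1 <- fitPS(d1, sc)@ps
        ps2 <- fitPS(d2, sc)@ps
        fit <- fitInteraction(d1, d2, y, ps1, ps2)
        both <- d1 == 1 & d2 == 1
        list(fit = fit, ea = expectedAdjusted(fit, ps1[both], ps2[both]),
             eu = expectedUnadjusted(fit, sum(both)))
      } else {
        fit <- fitInteraction(d1, d2, y)
        list(fit = fit, ea = NA_real_, eu = expectedUnadjusted(fit, sum(d1 & d2)))
      }
    }, ddiError = function(e) NULL)
    if (!is.null(res) && res$fit@converged) {
      conv[i] <- TRUE
      eAdj[i] <- res$ea
      eUn[i] <- res$eu
    }
  }
  scores$E_unadjusted <- eUn
  scores$E_adjusted <- eAdj
  scores$converged <- conv
  eMix <- if (psAdjust) eAdj else eUn
  usable <- conv & scores$N > 0 & is.finite(eMix) & eMix > 0
  mixture <- NULL
  if (sum(usable) >= 4L) {
    mixture <- fitConditional(scores$N[usable], eMix[usable])
    fdr <- rep(NA_real_, n)
    fdr[usable] <- adjustedFdr(mixture, scores$N[usable], eMix[usable])
    fdr[conv & scores$N == 0] <- 1
    scores$adjusted_fdr <- fdr
    scores$neg_log10_fdr <- -log10(fdr)
  }
  list(scores = scores, mixture = mixture)
}

## benchmark per-pair summarizer: PS-adjusted / unadjusted expectations from
## the true propensity scores plus Omega inputs, all computed before the
## report-level data is discarded
#' @keywords internal
.benchmarkSummarizer <- function(rep, cells) {
  both <- rep$d1 == 1 & rep$d2 == 1
  X <- cbind(1, rep$d1, rep$d2, rep$d1 * rep$d2, rep$ps1, rep$ps2)
  fit <- .irlsLogistic(X, rep$y)
  ok <- fit$converged && !fit$singular
  b <- fit$coefficients
  eAdj <- if (ok) sum(stats::plogis(b[1] + b[2] + b[3] +
                                    b[5] * rep$ps1[both] + b[6] * rep$ps2[both]))
          else NA_real_
  eUn <- if (ok) stats::plogis(b[1] + b[2] + b[3]) * sum(both) else NA_real_
  c(Eadj = eAdj, Eun = eUn, okFit = as.numeric(ok))
}

#' Run the simulation benchmark for PS-3CMM and Omega shrinkage
#'
#' Simulates a labelled study, scores every pair with both methods, fits the
#' conditional mixture on the PS-adjusted (N, E) pairs, and evaluates each
#' ranking by ROC AUC against the true labels. The PS-3CMM ranking is by
#' ascending adjusted-FDR (pairs with \code{N = 0} are assigned FDR 1; pairs
#' whose logistic fit failed are unscored and rank worst); the Omega ranking
#' is by descending \code{omega025}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param alpha Omega shrinkage prior parameter.
#' @return list with \code{pairs} (scored per-pair data.frame including
#'   \code{adjusted_fdr} and \code{omega025}), \code{mixture} (the
#'   \linkS4class{MixtureFit}), and \code{auc} (named vector: ps3cmm, omega).
#' @examples
#' cfg <- simConfig("a", nReports = 5000, nSignals = 30, nNegatives = 30,
#'                  seed = 1)
#' bench <- runBenchmark(cfg)
#' bench$auc
#' @export
runBenchmark <- function(config, alpha = 0.5) {
  study <- simulateStudy(config, summarize = .benchmarkSummarizer)
  pairs <- study@pairs
  r00 <- ifelse(pairs$a + pairs$b > 0, pairs$a / (pairs$a + pairs$b), NA_real_)
  r10 <- ifelse(pairs$c + pairs$d > 0, pairs$c / (pairs$c + pairs$d), NA_real_)
  r01 <- ifelse(pairs$e + pairs$f > 0, pairs$e / (pairs$e + pairs$f), NA_real_)
  pairs$E_additive <- .omegaExpectedCells(r00, r10, r01, pairs$g + pairs$h,
                                          strict = FALSE)
  om <- omegaStats(pairs$N, ifelse(is.na(pairs$E_additive), 0, pairs$E_additive),
                   alpha)
  pairs$omega <- ifelse(is.na(pairs$E_additive), NA_real_, om$omega)
  pairs$omega025 <- ifelse(is.na(pairs$E_additive), NA_real_, om$omega025)
  ok <- pairs$okFit == 1
  usable <- ok & pairs$N > 0 & is.finite(pairs$Eadj) & pairs$Eadj > 0
  mixture <- fitConditional(pairs$N[usable], pairs$Eadj[usable])
  fdr <- rep(NA_real_, nrow(pairs))
  fdr[usable] <- adjustedFdr(mixture, pairs$N[usable], pairs$Eadj[usable])
  fdr[ok & pairs$N == 0] <- 1
  pairs$adjusted_fdr <- fdr
  pairs$neg_log10_fdr <- -log10(fdr)
  labels <- pairs$label == "signal"
  auc <- c(ps3cmm = rocAuc(pairs$neg_log10_fdr, labels),
           omega = rocAuc(pairs$omega025, labels))
  list(pairs = pairs, mixture = mixture, auc = auc)
}
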