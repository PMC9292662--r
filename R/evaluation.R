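## Ranking and operating-characteristic evaluation of scored combinations.

#' ROC area under the curve by the midrank Mann-Whitney statistic
#'
#' Equals the Mann-Whitney U statistic normalized by
#' \code{nPos * nNeg}, with tied score pairs counted 1/2 (midrank /
#' trapezoidal convention, appropriate for the many exact ties produced by
#' discrete counts). Missing scores are treated as worst (tied at
#' \code{-Inf}): a method that cannot score a combination has not detected it.
#'
#' @param scores numeric scores, higher = stronger signal; NA allowed.
#' @param labels binary labels (1/TRUE = positive).
#' @return AUC in [0, 1].
#' @examples
#' rocAuc(c(3, 2, 1), c(1, 0, 0))
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    .stopCondition("ddiInputError", "scores and labels lengths differ")
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0L || nNeg == 0L)
    .stopCondition("ddiInputError", "both classes must be present")
  scores[is.na(scores)] <- -Inf
  r <- rank(scores)  # midranks
  (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Rank combinations by a method's score
#'
#' Orders a scored table descending by the given score column (higher =
#' stronger signal; rank adjusted-FDR by its negative log10). Ties are broken
#' deterministically by the id column; missing scores sort last.
#'
#' @param df data.frame of scored combinations.
#' @param scoreCol name of the score column.
#' @param idCol name of the identifier column used for the tie-break.
#' @return \code{df} reordered, with a \code{rank} column prepended.
#' @export
rankTable <- function(df, scoreCol, idCol = "pairId") {
  s <- df[[scoreCol]]
  if (is.null(s)) .stopCondition("ddiInputError", paste0("no column ", scoreCol))
  s[is.na(s)] <- -Inf
  ord <- order(-s, df[[idCol]])
  out <- df[ord, , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}

#' Compare the top-k signal lists of two methods
#'
#' Computes the overlap of the two top-k sets and, when cell counts are
#' available, the fraction of each method's top-k that is NPIRR / PIRR
#' (\code{\link{classifyPattern}}).
#'
#' @param rank1,rank2 ranked tables from \code{\link{rankTable}} over the same
#'   combination universe.
#' @param k list depth; must not exceed either table.
#' @param countsDf optional data.frame keyed by \code{idCol} with cell columns
#'   \code{a}..\code{f} for pattern classification.
#' @param idCol identifier column name.
#' @return list with \code{overlap} (integer) and, when counts are given,
#'   \code{patternFractions} (methods x {NPIRR, PIRR, undefined}).
#' @export
compareTopK <- function(rank1, rank2, k, countsDf = NULL, idCol = "pairId") {
  if (k > nrow(rank1) || k > nrow(rank2))
    .stopCondition("ddiInputError", "k exceeds the ranked universe")
  top1 <- rank1[[idCol]][seq_len(k)]
  top2 <- rank2[[idCol]][seq_len(k)]
  out <- list(overlap = length(intersect(top1, top2)))
  if (!is.null(countsDf)) {
    frac <- function(ids) {
      cls <- classifyPattern(countsDf[match(ids, countsDf[[idCol]]), , drop = FALSE])
      prop.table(table(cls))
    }
    out$patternFractions <- rbind(method1 = frac(top1), method2 = frac(top2))
  }
  out
}
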