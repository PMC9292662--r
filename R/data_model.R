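## Report-level data representation and 2x2x2 tabulation.
##
## A report table is a data.frame with columns:
##   report_id  opaque unique identifier
##   drugs      list column of character vectors (normalized drug names)
##   ades       list column of character vectors (ADE terms)
## readReports()/writeReports() serialize the two set columns pipe-delimited.

#' Read a report-level table from TSV
#'
#' Expects a UTF-8 TSV with a header row and columns \code{report_id},
#' \code{drugs}, \code{ades}; the latter two are pipe-delimited sets (empty
#' string for an empty set).
#'
#' @param path file path.
#' @return data.frame with list columns \code{drugs} and \code{ades}.
#' @examples
#' path <- system.file("extdata", "example_reports.tsv", package = "DDIsignal")
#' reports <- readReports(path)
#' counts(tabulateReports(reports, "warfarin", "tetracycline", "delirium"))
#' @export
readReports <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", fileEncoding = "UTF-8")
  need <- c("report_id", "drugs", "ades")
  if (!all(need %in% names(df)))
    .stopCondition("ddiInputError",
      paste0("report table must have columns ", paste(need, collapse = ", ")))
  if (anyDuplicated(df$report_id))
    .stopCondition("ddiInputError", "report_id values must be unique")
  splitSet <- function(x) {
    out <- strsplit(x, "|", fixed = TRUE)
    lapply(out, function(v) unique(v[nzchar(v)]))
  }
  data.frame(report_id = df$report_id,
             drugs = I(splitSet(df$drugs)),
             ades = I(splitSet(df$ades)),
             stringsAsFactors = FALSE)
}

#' Write a report-level table to TSV
#'
#' @param reports report data.frame as returned by \code{\link{readReports}}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeReports <- function(reports, path) {
  joinSet <- function(col) vapply(col, paste, character(1), collapse = "|")
  out <- data.frame(report_id = reports$report_id,
                    drugs = joinSet(reports$drugs),
                    ades = joinSet(reports$ades))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Cross-classify reports for one drug pair and ADE
#'
#' Each report contributes to exactly one of the eight cells according to
#' membership of the two drugs and the ADE in its sets; the cells therefore sum
#' to the number of reports. The pair is unordered: drug labels are
#' canonicalized lexicographically before tabulation.
#'
#' @param reports report data.frame (list columns \code{drugs}, \code{ades}).
#' @param drug1,drug2 distinct drug identifiers.
#' @param ade ADE identifier.
#' @return a \linkS4class{ContingencyTable}.
#' @examples
#' reports <- data.frame(report_id = "r1",
#'                       drugs = I(list(c("A", "B"))), ades = I(list("ADE")))
#' counts(tabulateReports(reports, "A", "B", "ADE"))  # g = 1
#' @export
tabulateReports <- function(reports, drug1, drug2, ade) {
  if (drug1 == drug2)
    .stopCondition("ddiInputError", "drug1 and drug2 must differ")
  if (drug2 < drug1) { tmp <- drug1; drug1 <- drug2; drug2 <- tmp }
  d1 <- vapply(reports$drugs, function(s) drug1 %in% s, logical(1))
  d2 <- vapply(reports$drugs, function(s) drug2 %in% s, logical(1))
  yy <- vapply(reports$ades, function(s) ade %in% s, logical(1))
  cells <- .tabulateExposure(d1, d2, yy)
  do.call(ContingencyTable,
          c(as.list(cells), list(drug1 = drug1, drug2 = drug2, ade = ade)))
}

## shared cell counter over three logical vectors
#' @keywords internal
.tabulateExposure <- function(d1, d2, y) {
  idx <- 1L + d1 * 1L + d2 * 2L           # 1: none, 2: d1, 3: d2, 4: both
  ade <- tabulate(idx[y], nbins = 4L)
  no <- tabulate(idx[!y], nbins = 4L)
  c(a = ade[1], b = no[1], c = ade[2], d = no[2],
    e = ade[3], f = no[3], g = ade[4], h = no[4])
}

#' Enumerate drug pairs above a co-occurrence frequency threshold
#'
#' Returns every unordered drug pair whose co-report count (the number of
#' reports mentioning both drugs, i.e. \code{g + h}) is strictly greater than
#' \code{minPairFreq}, optionally crossed with a set of ADEs.
#'
#' @param reports report data.frame.
#' @param minPairFreq non-negative integer threshold; a pair is retained only
#'   when its count exceeds it (strict inequality).
#' @param ades optional character vector of ADE terms to cross with the pairs.
#' @return data.frame with columns \code{drug1}, \code{drug2} (canonical
#'   order), \code{nPair}, and \code{ade} when \code{ades} is given.
#' @export
enumeratePairs <- function(reports, minPairFreq = 50L, ades = NULL) {
  if (minPairFreq < 0)
    .stopCondition("ddiInputError", "minPairFreq must be non-negative")
  pairCounts <- new.env(parent = emptyenv())
  for (s in reports$drugs) {
    s <- sort(unique(s))
    n <- length(s)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      key <- paste(s[i], s[j], sep = "\r")
      prev <- pairCounts[[key]]
      pairCounts[[key]] <- if (is.null(prev)) 1L else prev + 1L
    }
  }
  keys <- ls(pairCounts)
  cnt <- vapply(keys, function(k) pairCounts[[k]], integer(1))
  keep <- cnt > minPairFreq
  parts <- strsplit(keys[keep], "\r", fixed = TRUE)
  out <- data.frame(
    drug1 = vapply(parts, `[`, character(1), 1L),
    drug2 = vapply(parts, `[`, character(1), 2L),
    nPair = unname(cnt[keep]))
  out <- out[order(out$drug1, out$drug2), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(ades) && nrow(out) > 0L) {
    out <- merge(out, data.frame(ade = ades), by = NULL)
    out <- out[order(out$drug1, out$drug2, out$ade), , drop = FALSE]
    rownames(out) <- NULL
  } else if (!is.null(ades)) {
    out$ade <- character(0)
  }
  out
}

#' Tabulate all retained drug-pair / ADE combinations
#'
#' Convenience composition of \code{\link{enumeratePairs}} and
#' \code{\link{tabulateReports}} producing one row of cell counts per
#' combination.
#'
#' @inheritParams enumeratePairs
#' @param ades character vector of ADE terms (required here).
#' @return data.frame with drug1, drug2, ade, nPair and cells a..h.
#' @export
tabulateCombinations <- function(reports, ades, minPairFreq = 50L) {
  pairs <- enumeratePairs(reports, minPairFreq = minPairFreq, ades = ades)
  if (nrow(pairs) == 0L) {
    return(cbind(pairs, as.data.frame(matrix(numeric(0), 0, 8,
      dimnames = list(NULL, letters[1:8])))))
  }
  cells <- t(vapply(seq_len(nrow(pairs)), function(i) {
    counts(tabulateReports(reports, pairs$drug1[i], pairs$drug2[i], pairs$ade[i]))
  }, numeric(8)))
  cbind(pairs, as.data.frame(cells))
}

#' @describeIn counts cell counts of a single table
#' @export
setMethod("counts", "ContingencyTable", function(object) object@counts)

#' @describeIn reportingRates rates with NA for zero denominators
#' @export
setMethod("reportingRates", "ContingencyTable", function(object) {
  ct <- object@counts
  den <- c(ct["a"] + ct["b"], ct["c"] + ct["d"], ct["e"] + ct["f"], ct["g"] + ct["h"])
  num <- ct[c("a", "c", "e", "g")]
  r <- ifelse(den > 0, num / den, NA_real_)
  stats::setNames(as.numeric(r), c("r00", "r10", "r01", "r11"))
})

#' @describeIn observedN the g cell
#' @export
setMethod("observedN", "ContingencyTable", function(object) unname(object@counts["g"]))

#' @describeIn classifyPattern single table
#' @export
setMethod("classifyPattern", "ContingencyTable", function(object) {
  ct <- object@counts
  .classifyPatternCells(ct["a"], ct["b"], ct["c"], ct["d"], ct["e"], ct["f"])
})

#' @describeIn classifyPattern vectorized over a data.frame with columns a..f
#' @export
setMethod("classifyPattern", "data.frame", function(object) {
  .classifyPatternCells(object$a, object$b, object$c, object$d, object$e, object$f)
})

#' @keywords internal
.classifyPatternCells <- function(a, b, c, d, e, f) {
  r00 <- ifelse(a + b > 0, a / (a + b), NA_real_)
  r10 <- ifelse(c + d > 0, c / (c + d), NA_real_)
  r01 <- ifelse(e + f > 0, e / (e + f), NA_real_)
  out <- ifelse(is.na(r00) | is.na(r10) | is.na(r01), "undefined",
         ifelse(r10 - r00 <= 0 | r01 - r00 <= 0, "NPIRR", "PIRR"))
  factor(out, levels = c("NPIRR", "PIRR", "undefined"))
}

#' Read per-combination contingency counts from TSV
#'
#' Columns: \code{drug1}, \code{drug2}, \code{ade}, \code{a}..\code{h}.
#'
#' @param path file path.
#' @return data.frame of combinations and cell counts.
#' @export
readContingency <- function(path) {
  df <- utils::read.delim(path, fileEncoding = "UTF-8")
  need <- c("drug1", "drug2", "ade", letters[1:8])
  if (!all(need %in% names(df)))
    .stopCondition("ddiInputError",
      paste0("contingency table must have columns ", paste(need, collapse = ", ")))
  bad <- which(rowSums(is.na(df[letters[1:8]]) | df[letters[1:8]] < 0) > 0)
  if (length(bad))
    .stopCondition("ddiInputError",
      paste0("malformed counts on data row(s) ", paste(bad, collapse = ", ")))
  df
}

#' Write per-combination scores or counts to TSV
#'
#' @param df data.frame to serialize.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeScores <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

setMethod("show", "ContingencyTable", function(object) {
  ct <- object@counts
  lab <- if (!is.na(object@drug1))
    paste0(object@drug1, " x ", object@drug2, " / ", object@ade) else "unlabelled"
  cat("ContingencyTable (", lab, ")\n", sep = "")
  m <- matrix(ct, 4, 2, byrow = TRUE,
              dimnames = list(c("neither", "drug1 only", "drug2 only", "both"),
                              c("ADE", "no ADE")))
  print(m)
  r <- reportingRates(object)
  cat("rates:", paste(names(r), format(r, digits = 4), sep = "=", collapse = "  "),
      "\n")
})
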