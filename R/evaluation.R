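#' Score a ranked edge list against a gold standard
#'
#' Computes AUROC and AUPR of the absolute-score ranking over the full
#' candidate set (all ordered pairs of distinct genes in the gold-standard
#' universe). AUROC uses the tie-corrected Mann-Whitney formulation
#' (tied scores contribute fractionally); AUPR is the step-wise
#' precision-recall integral with no interpolation across recall gaps,
#' i.e. the sum over score thresholds of precision times recall increment.
#'
#' @param ranking an \linkS4class{EdgeScoreTable} covering exactly the
#'   candidate pairs of the gold universe.
#' @param gold a \linkS4class{GoldStandard} with at least one true edge.
#' @return An \linkS4class{EvalResult}.
#' @export
evaluateRanking <- function(ranking, gold) {
  stopifnot(is(ranking, "EdgeScoreTable"), is(gold, "GoldStandard"))
  genes <- gold@universe
  G <- length(genes)
  cand <- expand.grid(target = genes, regulator = genes,
                      stringsAsFactors = FALSE)
  cand <- cand[cand$regulator != cand$target, c("regulator", "target")]
  candKey <- paste(cand$regulator, cand$target, sep = "\r")
  e <- ranking@entries
  key <- paste(e$regulator, e$target, sep = "\r")
  if (anyDuplicated(key))
    stopData("ranking contains duplicate pairs")
  missing <- setdiff(candKey, key)
  if (length(missing))
    stopData("ranking is missing candidate pair(s), e.g. ",
             sub("\r", " -> ", missing[1L], fixed = TRUE))
  extra <- setdiff(key, candKey)
  if (length(extra))
    stopData("ranking contains non-candidate pair(s), e.g. ",
             sub("\r", " -> ", extra[1L], fixed = TRUE))
  truth <- key %in% paste(gold@edges[, 1L], gold@edges[, 2L], sep = "\r")
  nTrue <- sum(truth)
  nCand <- length(key)
  if (nTrue == 0L)
    stopData("gold standard has no true edges (AUPR undefined)")
  if (nTrue == nCand)
    stopData("gold standard has no negative pairs (AUROC undefined)")
  m <- rankingMetrics(abs(e$score), truth)
  new("EvalResult", auroc = m$auroc, aupr = m$aupr,
      nTrue = as.integer(nTrue), nCandidates = as.integer(nCand),
      rocPoints = m$rocPoints, prPoints = m$prPoints)
}

#' AUROC and AUPR of a scored label vector
#'
#' The metric core behind [evaluateRanking()], usable on any scores and
#' binary labels. AUROC is the tie-corrected Mann-Whitney statistic
#' (larger scores rank first, tied scores contribute fractionally); AUPR
#' is the step-wise precision-recall integral, i.e. the sum over score
#' thresholds of precision times recall increment, with no interpolation
#' across recall gaps.
#'
#' @param scores numeric ranking statistic (already on the scale to rank
#'   by, e.g. absolute edge scores).
#' @param labels logical vector, TRUE for positives.
#' @return list(auroc, aupr, rocPoints, prPoints).
#' @examples
#' rankingMetrics(c(4, 3, 2, 1), c(TRUE, FALSE, TRUE, FALSE))$auroc  # 0.75
#' @export
rankingMetrics <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), is.logical(labels))
  nTrue <- sum(labels)
  nAll <- length(labels)
  if (nTrue == 0L || nTrue == nAll)
    stopData("need at least one positive and one negative label")
  rk <- rank(scores, ties.method = "average")
  aurocVal <- (sum(rk[labels]) - nTrue * (nTrue + 1) / 2) /
    (nTrue * (nAll - nTrue))
  # threshold sweep over distinct score values, descending
  o <- order(-scores)
  sOrd <- scores[o]; tOrd <- labels[o]
  last <- !duplicated(sOrd, fromLast = TRUE)  # last index of each tie block
  TP <- cumsum(tOrd)[last]
  FP <- cumsum(!tOrd)[last]
  tpr <- TP / nTrue
  fpr <- FP / (nAll - nTrue)
  prec <- TP / (TP + FP)
  auprVal <- sum(diff(c(0, tpr)) * prec)
  list(auroc = aurocVal, aupr = auprVal,
       rocPoints = data.frame(fpr = c(0, fpr), tpr = c(0, tpr)),
       prPoints = data.frame(recall = c(0, tpr),
                             precision = c(prec[1L], prec)))
}

#' Evaluate ranked-edge and gold-standard files
#'
#' File-level composition of [readEdgeRanking()], [readGoldStandard()] and
#' [evaluateRanking()]; identical to the in-memory path.
#'
#' @param rankingPath path to a ranked-edges TSV.
#' @param goldPath path to a gold-standard TSV.
#' @param genes the gene universe.
#' @return An \linkS4class{EvalResult}.
#' @export
evaluateFiles <- function(rankingPath, goldPath, genes) {
  evaluateRanking(readEdgeRanking(rankingPath),
                  readGoldStandard(goldPath, genes))
}

#' Write an evaluation result as TSV
#'
#' @param result an \linkS4class{EvalResult}.
#' @param path output path for the two-line metric table.
#' @param curves optional path prefix; when set, writes
#'   `<curves>_roc.tsv` and `<curves>_pr.tsv`.
#' @return Invisibly, `path`.
#' @export
writeEvalResult <- function(result, path, curves = NULL) {
  df <- data.frame(metric = c("auroc", "aupr"),
                   value = c(result@auroc, result@aupr))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  if (!is.null(curves)) {
    write.table(result@rocPoints, paste0(curves, "_roc.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(result@prPoints, paste0(curves, "_pr.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
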