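#' Cluster-level interaction scores
#'
#' Converts the fitted Gaussian posterior over the transition matrix into
#' a signed score for every directed cluster pair: the posterior mean of
#' the transition element mapping cluster j at time t to cluster k at time
#' t+1, divided by its posterior standard deviation. Rows of the returned
#' matrix index the regulating cluster j, columns the target cluster k.
#'
#' @param state a fitted \linkS4class{BaconFit}.
#' @return A K x K numeric matrix of signed scores.
#' @export
clusterScores <- function(state) {
  K <- state@config@K
  scores <- matrix(0, K, K)
  for (tgt in seq_len(K)) {
    v <- diag(state@qB$cov[[tgt]])[seq_len(K)]
    if (any(v <= 0))
      stop(errorCondition(
        "zero posterior variance in a transition element (degenerate fit)",
        class = c("baconetNumericalError", "error")))
    # row `tgt` of the transition matrix holds the coefficients feeding
    # cluster `tgt`; entry j is the influence of regulating cluster j
    scores[, tgt] <- state@qB$mean[tgt, seq_len(K)] / sqrt(v)
  }
  scores
}

#' Gene-level ranked edge table
#'
#' Assigns every ordered pair of distinct genes the score of its cluster
#' pair under the hard membership assignment (argmax responsibilities,
#' ties to the lowest cluster index). Pairs within one cluster receive
#' that cluster's self-interaction score. The table is sorted by
#' descending absolute score, ties broken by (regulator, target) in
#' C-locale lexicographic order.
#'
#' @param state a fitted \linkS4class{BaconFit}.
#' @param geneNames gene identifiers; defaults to the fit's genes. Must
#'   match the genes the model was fitted to.
#' @param soft use responsibility-weighted expected scores instead of hard
#'   assignments (default off; the model's memberships are one-hot).
#' @param includeWithinCluster keep pairs of genes sharing a cluster
#'   (default TRUE, the reference behaviour); set FALSE to drop them,
#'   shrinking the table below G(G-1) entries.
#' @return An \linkS4class{EdgeScoreTable} with G(G-1) entries (fewer if
#'   `includeWithinCluster = FALSE`).
#' @export
geneRanking <- function(state, geneNames = NULL, soft = FALSE,
                        includeWithinCluster = TRUE) {
  if (is.null(geneNames)) geneNames <- state@geneNames
  if (!all(geneNames %in% state@geneNames) ||
      length(geneNames) != length(state@geneNames))
    stop("gene names do not match the fitted model")
  S <- clusterScores(state)
  G <- length(geneNames)
  idx <- match(geneNames, state@geneNames)
  reg <- rep(seq_len(G), each = G)
  tgt <- rep(seq_len(G), times = G)
  keep <- reg != tgt
  reg <- reg[keep]; tgt <- tgt[keep]
  z <- max.col(state@qZ, ties.method = "first")[idx]
  if (!includeWithinCluster) {
    cross <- z[reg] != z[tgt]
    reg <- reg[cross]; tgt <- tgt[cross]
  }
  if (soft) {
    R <- state@qZ[idx, , drop = FALSE]
    score <- rowSums((R[reg, , drop = FALSE] %*% S) * R[tgt, , drop = FALSE])
  } else {
    score <- S[cbind(z[reg], z[tgt])]
  }
  e <- data.frame(regulator = geneNames[reg], target = geneNames[tgt],
                  score = score, stringsAsFactors = FALSE)
  e <- e[cOrder(-abs(e$score), e$regulator, e$target), , drop = FALSE]
  rownames(e) <- NULL
  new("EdgeScoreTable", entries = e, bestK = state@config@K,
      clusterScores = S)
}
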