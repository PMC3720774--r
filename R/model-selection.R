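#' Restart-by-cluster-count model selection
#'
#' Fits the model for every combination of cluster count and random
#' restart and selects the fit with the highest final evidence lower
#' bound (the variational estimate of the marginal likelihood). Each
#' (K, restart) pair receives a deterministic seed derived from
#' `baseSeed`, so the sweep is reproducible and the result does not
#' depend on execution order. Individual fits that abort numerically are
#' recorded as failed and excluded from selection.
#'
#' @param data a \linkS4class{TimeSeriesSet}.
#' @param KValues cluster counts to try, each in 1..G.
#' @param restarts number of random restarts per cluster count
#'   (default 10).
#' @param baseSeed integer seed from which per-fit seeds are derived.
#' @param config a \linkS4class{BaconConfig} template; its K and seed are
#'   overridden per fit.
#' @param earlyStop stop the K sweep once the best ELBO over a cluster
#'   count has fallen below the running best for `patience` consecutive
#'   counts (default off: exhaustive sweep).
#' @param patience consecutive below-best counts tolerated when
#'   `earlyStop` is on.
#' @return A \linkS4class{BaconSweep}.
#' @export
baconSweep <- function(data, KValues, restarts = 10L, baseSeed = 1L,
                       config = baconConfig(K = 1L), earlyStop = FALSE,
                       patience = 2L) {
  G <- nGenes(data)
  KValues <- as.integer(KValues)
  if (any(KValues < 1L | KValues > G))
    stop("all cluster counts must lie in 1..G")
  if (restarts < 1L) stop("need at least one restart")
  records <- data.frame(K = integer(), seed = integer(), elbo = numeric(),
                        converged = logical(), sweeps = integer(),
                        ok = logical())
  best <- NULL
  bestElbo <- -Inf
  runningBestByK <- -Inf
  lag <- 0L
  for (K in KValues) {
    bestAtK <- -Inf
    for (r in seq_len(restarts)) {
      seed <- comboSeed(baseSeed, K, r)
      cfg <- config
      cfg@K <- K
      cfg@seed <- seed
      if (!is.null(cfg@clampMemberships) && K != G)
        stop("clamped memberships require K equal to the number of genes")
      fit <- tryCatch(baconFit(data, cfg), baconetNumericalError = function(e) e)
      failed <- inherits(fit, "error")
      elbo <- if (failed) NA_real_ else finalELBO(fit)
      records[nrow(records) + 1L, ] <-
        list(K, seed, elbo, if (failed) FALSE else fit@converged,
             if (failed) NA_integer_ else fit@nSweeps, !failed)
      if (!failed) {
        bestAtK <- max(bestAtK, elbo)
        if (elbo > bestElbo) {
          bestElbo <- elbo
          best <- fit
        }
      }
    }
    if (earlyStop) {
      if (bestAtK < runningBestByK) lag <- lag + 1L else lag <- 0L
      runningBestByK <- max(runningBestByK, bestAtK)
      if (lag >= patience) break
    }
  }
  if (is.null(best)) stop("every fit in the sweep failed")
  new("BaconSweep", records = records, best = best,
      bestK = best@config@K)
}

#' Gap between the best and second-best cluster count
#'
#' Reports the difference between the winning final ELBO and the best
#' final ELBO achieved at any other cluster count. A small gap means a
#' competing cluster count explains the data almost as well; the value is
#' reported for diagnostics only and plays no role in selection.
#'
#' @param result a \linkS4class{BaconSweep} covering at least two cluster
#'   counts.
#' @return A single non-negative numeric value.
#' @export
likelihoodGap <- function(result) {
  rec <- result@records[result@records$ok, ]
  other <- rec[rec$K != result@bestK, ]
  if (!nrow(other))
    stop("likelihoodGap needs a successful fit at a different cluster count")
  max(rec$elbo[rec$K == result@bestK]) - max(other$elbo)
}

#' Export sweep records as TSV
#'
#' @param result a \linkS4class{BaconSweep}.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeSweepRecords <- function(result, path) {
  write.table(result@records, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
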