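#' Accessors for baconet objects
#'
#' Small read-only accessors exposing the contents of the S4 containers
#' without touching slots directly.
#'
#' @param x an object of the documented class.
#' @param i series index.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
setMethod("geneNames", "ExpressionSeries", function(x) x@geneNames)
#' @rdname accessors
setMethod("geneNames", "TimeSeriesSet", function(x) x@series[[1L]]@geneNames)
#' @rdname accessors
setMethod("geneNames", "BaconFit", function(x) x@geneNames)

#' @rdname accessors
setMethod("nGenes", "TimeSeriesSet", function(x) length(geneNames(x)))
#' @rdname accessors
setMethod("nSeries", "TimeSeriesSet", function(x) length(x@series))
#' @rdname accessors
setMethod("nTimePoints", "TimeSeriesSet",
          function(x) vapply(x@series, function(s) length(s@timePoints), 1L))

#' @rdname accessors
setMethod("seriesValues", "TimeSeriesSet", function(x, i = 1L) x@series[[i]]@values)

#' @rdname accessors
setMethod("trueEdges", "GoldStandard", function(x) x@edges)
#' @rdname accessors
setMethod("geneUniverse", "GoldStandard", function(x) x@universe)

#' @rdname accessors
setMethod("responsibilities", "BaconFit", function(x) x@qZ)

#' @rdname accessors
setMethod("memberships", "BaconFit", function(x) {
  # argmax responsibilities; ties resolved to the lowest cluster index
  z <- max.col(x@qZ, ties.method = "first")
  names(z) <- x@geneNames
  z
})

#' @rdname accessors
setMethod("elboTrace", "BaconFit", function(x) x@elboTrace)
#' @rdname accessors
setMethod("finalELBO", "BaconFit", function(x) {
  if (length(x@elboTrace)) x@elboTrace[length(x@elboTrace)] else NA_real_
})

#' @rdname accessors
setMethod("bestModel", "BaconSweep", function(x) x@best)
#' @rdname accessors
setMethod("bestK", "BaconSweep", function(x) x@bestK)
#' @rdname accessors
setMethod("sweepRecords", "BaconSweep", function(x) x@records)

#' @rdname accessors
setMethod("edgeEntries", "EdgeScoreTable", function(x) x@entries)
#' @rdname accessors
setMethod("bestK", "EdgeScoreTable", function(x) x@bestK)

#' @rdname accessors
setMethod("auroc", "EvalResult", function(x) x@auroc)
#' @rdname accessors
setMethod("aupr", "EvalResult", function(x) x@aupr)

setMethod("show", "ExpressionSeries", function(object) {
  cat("ExpressionSeries:", length(object@geneNames), "genes x",
      length(object@timePoints), "time points")
  if (length(object@replicates))
    cat(",", length(object@replicates), "extra replicate(s)")
  cat("\n")
})

setMethod("show", "TimeSeriesSet", function(object) {
  cat("TimeSeriesSet '", object@networkId, "': ",
      length(object@series), " series, ", nGenes(object), " genes\n", sep = "")
  for (s in object@series)
    cat("  ", length(s@timePoints), " time points, ",
        1L + length(s@replicates), " replicate(s)\n", sep = "")
})

setMethod("show", "GoldStandard", function(object) {
  n <- length(object@universe)
  cat("GoldStandard:", nrow(object@edges), "true edges over",
      n * (n - 1L), "candidate pairs (", n, "genes )\n")
})

setMethod("show", "BaconConfig", function(object) {
  cat("BaconConfig: K =", object@K, ", maxSweeps =", object@maxSweeps,
      ", relTol =", object@relTol, ", seed =", object@seed, "\n")
  if (!is.null(object@clampMemberships)) cat("  memberships clamped\n")
})

setMethod("show", "BaconFit", function(object) {
  cat("BaconFit: K =", object@config@K, ",", length(object@geneNames),
      "genes,", length(object@qX), "series\n")
  cat("  sweeps:", object@nSweeps,
      if (object@converged) "(converged)" else "(not converged)", "\n")
  cat("  final ELBO:", format(finalELBO(object), digits = 8), "\n")
})

setMethod("show", "BaconSweep", function(object) {
  cat("BaconSweep:", nrow(object@records), "fits over K in {",
      paste(sort(unique(object@records$K)), collapse = ", "), "}\n")
  cat("  selected K =", object@bestK, "with ELBO",
      format(finalELBO(object@best), digits = 8), "\n")
})

setMethod("show", "EdgeScoreTable", function(object) {
  cat("EdgeScoreTable:", nrow(object@entries), "directed pairs, K =",
      object@bestK, "\n")
  print(head(object@entries, 5L), row.names = FALSE)
  if (nrow(object@entries) > 5L) cat("  ...\n")
})

setMethod("show", "EvalResult", function(object) {
  cat("EvalResult: AUROC =", format(object@auroc, digits = 4),
      ", AUPR =", format(object@aupr, digits = 4), "(",
      object@nTrue, "true /", object@nCandidates, "candidates )\n")
})

setMethod("show", "SimSpec", function(object) {
  cat("SimSpec: K =", object@K, ", G =", object@G, ", T =", object@T,
      ",", object@nSeries, "series,", object@nReplicates, "replicate(s)\n")
})

setMethod("show", "GenerativeParams", function(object) {
  cat("GenerativeParams: K =", object@K, ", G =", object@G, ";",
      sum(object@B != 0), "nonzero transition entries\n")
})
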