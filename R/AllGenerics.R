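#' @rdname accessors
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))

#' @rdname accessors
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' @rdname accessors
#' @export
setGeneric("nSeries", function(x) standardGeneric("nSeries"))

#' @rdname accessors
#' @export
setGeneric("nTimePoints", function(x) standardGeneric("nTimePoints"))

#' @rdname accessors
#' @export
setGeneric("seriesValues", function(x, i = 1L) standardGeneric("seriesValues"))

#' @rdname accessors
#' @export
setGeneric("trueEdges", function(x) standardGeneric("trueEdges"))

#' @rdname accessors
#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))

#' @rdname accessors
#' @export
setGeneric("responsibilities", function(x) standardGeneric("responsibilities"))

#' @rdname accessors
#' @export
setGeneric("memberships", function(x) standardGeneric("memberships"))

#' @rdname accessors
#' @export
setGeneric("elboTrace", function(x) standardGeneric("elboTrace"))

#' @rdname accessors
#' @export
setGeneric("finalELBO", function(x) standardGeneric("finalELBO"))

#' @rdname accessors
#' @export
setGeneric("bestModel", function(x) standardGeneric("bestModel"))

#' @rdname accessors
#' @export
setGeneric("bestK", function(x) standardGeneric("bestK"))

#' @rdname accessors
#' @export
setGeneric("sweepRecords", function(x) standardGeneric("sweepRecords"))

#' @rdname accessors
#' @export
setGeneric("edgeEntries", function(x) standardGeneric("edgeEntries"))

#' @rdname accessors
#' @export
setGeneric("auroc", function(x) standardGeneric("auroc"))

#' @rdname accessors
#' @export
setGeneric("aupr", function(x) standardGeneric("aupr"))
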