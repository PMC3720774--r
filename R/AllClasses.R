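setClassUnion("integerOrNULL", c("integer", "NULL"))
setClassUnion("listOrNULL", c("list", "NULL"))

#' Single time-course expression series
#'
#' One experiment's worth of observations for a network: an expression value
#' for every gene at every time point, optionally with technical replicates
#' of identical shape.
#'
#' @slot geneNames character vector of gene identifiers (case-sensitive,
#'   order-preserving).
#' @slot timePoints strictly increasing numeric time stamps (read from the
#'   input but treated as uniform steps by the model).
#' @slot values numeric matrix, genes x time points.
#' @slot replicates list of additional genes x time matrices (technical
#'   replicates); may be empty.
#' @export
setClass("ExpressionSeries",
  representation(geneNames = "character", timePoints = "numeric",
                 values = "matrix", replicates = "list"))

setValidity("ExpressionSeries", function(object) {
  g <- object@geneNames; tp <- object@timePoints; v <- object@values
  msgs <- character()
  if (length(tp) < 2L) msgs <- c(msgs, "need at least 2 time points")
  if (any(diff(tp) <= 0)) msgs <- c(msgs, "time points must be strictly increasing")
  if (nrow(v) != length(g) || ncol(v) != length(tp))
    msgs <- c(msgs, "values matrix must be genes x time points")
  if (anyNA(v) || !is.numeric(v)) msgs <- c(msgs, "values must be numeric with no missing entries")
  if (anyDuplicated(g)) msgs <- c(msgs, "duplicate gene names")
  for (r in object@replicates) {
    if (!identical(dim(r), dim(v))) msgs <- c(msgs, "replicate matrix shape mismatch")
    if (anyNA(r)) msgs <- c(msgs, "replicate has missing entries")
  }
  if (length(msgs)) msgs else TRUE
})

#' Set of time-course series from one network
#'
#' All observed series for a single gene regulatory network. Every series
#' must carry the same genes in the same order; the model shares the
#' cluster-level dynamics and the gene memberships across series while
#' inferring states and noise precisions per series.
#'
#' @slot series list of \linkS4class{ExpressionSeries}.
#' @slot networkId free-text label.
#' @export
setClass("TimeSeriesSet",
  representation(series = "list", networkId = "character"))

setValidity("TimeSeriesSet", function(object) {
  if (!length(object@series)) return("series list must be non-empty")
  if (!all(vapply(object@series, is, TRUE, "ExpressionSeries")))
    return("all elements must be ExpressionSeries")
  g1 <- object@series[[1L]]@geneNames
  for (s in object@series)
    if (!identical(s@geneNames, g1))
      return("all series must share the same gene names in the same order")
  TRUE
})

#' Gold standard of true directed edges
#'
#' The set of known true regulator -> target edges over a gene universe.
#' Every ordered pair of distinct genes not listed as true is a negative;
#' self-edges are excluded from the candidate set.
#'
#' @slot edges two-column character matrix (regulator, target) of true edges.
#' @slot universe character vector of all gene identifiers.
#' @export
setClass("GoldStandard",
  representation(edges = "matrix", universe = "character"))

setValidity("GoldStandard", function(object) {
  e <- object@edges
  if (ncol(e) != 2L) return("edges must have two columns")
  if (nrow(e)) {
    if (any(e[, 1L] == e[, 2L])) return("self-edges are not allowed")
    if (!all(e %in% object@universe)) return("edge gene not in universe")
    if (anyDuplicated(paste(e[, 1L], e[, 2L], sep = "\r")))
      return("duplicate edges")
  }
  if (anyDuplicated(object@universe)) return("duplicate genes in universe")
  TRUE
})

#' Model configuration for a variational fit
#'
#' @slot K number of clusters.
#' @slot maxSweeps maximum number of coordinate-ascent sweeps.
#' @slot relTol relative change in the evidence lower bound below which the
#'   fit is declared converged.
#' @slot seed integer seed controlling the randomised initialisation.
#' @slot a0,b0 initial shape and rate of the gamma hyperprior shared by
#'   the observation and state-noise precisions; re-estimated during the
#'   fit by marginal-likelihood maximisation.
#' @slot ardInit initial automatic-relevance-determination prior precision
#'   for the transition coefficients, trends and initial states.
#' @slot ardBounds length-2 clip range for evidence-maximised precisions.
#' @slot clampMemberships optional fixed cluster index per gene; when set,
#'   memberships are not inferred (the "no clustering" mode uses the
#'   identity map with K equal to the number of genes).
#' @slot standardize standardise each gene within each series to zero mean,
#'   unit variance before fitting.
#' @export
setClass("BaconConfig",
  representation(K = "integer", maxSweeps = "integer", relTol = "numeric",
                 seed = "integer", a0 = "numeric", b0 = "numeric",
                 ardInit = "numeric", ardBounds = "numeric",
                 clampMemberships = "integerOrNULL", standardize = "logical"))

setValidity("BaconConfig", function(object) {
  msgs <- character()
  if (object@K < 1L) msgs <- c(msgs, "K must be >= 1")
  if (object@maxSweeps < 0L) msgs <- c(msgs, "maxSweeps must be >= 0")
  if (object@relTol <= 0) msgs <- c(msgs, "relTol must be > 0")
  if (object@a0 <= 0 || object@b0 <= 0) msgs <- c(msgs, "a0, b0 must be > 0")
  if (object@ardInit <= 0) msgs <- c(msgs, "ardInit must be > 0")
  if (length(object@ardBounds) != 2L || object@ardBounds[1L] >= object@ardBounds[2L])
    msgs <- c(msgs, "ardBounds must be (min, max) with min < max")
  if (!is.null(object@clampMemberships) &&
      any(object@clampMemberships < 1L | object@clampMemberships > object@K))
    msgs <- c(msgs, "clamped memberships must lie in 1..K")
  if (length(msgs)) msgs else TRUE
})

#' Variational posterior state of a fit
#'
#' Holds every factor of the mean-field posterior together with the
#' evidence-lower-bound trace. Factors: per-row Gaussian posteriors over the
#' augmented transition rows (B_j, d_j); per-series, per-time-point Gaussian
#' posteriors over the cluster states; per-gene membership responsibilities;
#' per-series gamma posteriors over the observation precision; per-series,
#' per-cluster gamma posteriors over the state-noise precisions; and the
#' point-estimated ARD prior precisions.
#'
#' @slot qB list(mean = K x (K+1) matrix of row means, cov = list of K
#'   (K+1) x (K+1) covariance matrices). Column K+1 is the trend term.
#' @slot qX per-series list(M = K x T mean matrix, S = list of T K x K
#'   marginal covariance matrices, C = list of T-1 first-lag
#'   cross-covariances Cov(x_t, x_{t+1}), H = joint entropy of the state
#'   chain).
#' @slot qZ G x K responsibility matrix; rows sum to one.
#' @slot qTau S x 2 matrix (shape, rate) of gamma posteriors.
#' @slot qRho per-series list of K x 2 (shape, rate) matrices.
#' @slot ard list(B = K x K matrix, d = length-K vector, x0 = length-K
#'   vector) of point-estimated prior precisions, plus gamma = c(a0, b0),
#'   the evidence-maximised shared gamma hyperprior of the precisions.
#' @slot elboTrace one evidence-lower-bound value per completed sweep.
#' @slot converged logical.
#' @slot nSweeps number of completed sweeps.
#' @slot geneNames gene identifiers in data order.
#' @slot config the \linkS4class{BaconConfig} used.
#' @export
setClass("BaconFit",
  representation(qB = "list", qX = "list", qZ = "matrix", qTau = "matrix",
                 qRho = "list", ard = "list", elboTrace = "numeric",
                 converged = "logical", nSweeps = "integer",
                 geneNames = "character", config = "BaconConfig"))

setValidity("BaconFit", function(object) {
  msgs <- character()
  if (nrow(object@qZ) && max(abs(rowSums(object@qZ) - 1)) > 1e-12)
    msgs <- c(msgs, "responsibility rows must sum to 1")
  if (any(object@qTau <= 0)) msgs <- c(msgs, "gamma parameters must be > 0")
  for (r in object@qRho) if (any(r <= 0)) msgs <- c(msgs, "gamma parameters must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Result of a restart-by-cluster-count model-selection sweep
#'
#' @slot records data.frame with one row per (K, restart): K, seed, elbo,
#'   converged, sweeps, ok.
#' @slot best the winning \linkS4class{BaconFit} (highest final bound).
#' @slot bestK selected number of clusters.
#' @export
setClass("BaconSweep",
  representation(records = "data.frame", best = "BaconFit", bestK = "integer"))

#' Ranked table of directed gene-gene interaction scores
#'
#' Each of the G(G-1) ordered gene pairs receives the signed score of its
#' cluster pair (posterior mean of the corresponding transition element
#' divided by its posterior standard deviation), ranked by absolute value.
#'
#' @slot entries data.frame(regulator, target, score) in descending
#'   absolute-score order.
#' @slot bestK number of clusters behind the scores.
#' @slot clusterScores K x K signed score matrix (rows: regulating cluster).
#' @export
setClass("EdgeScoreTable",
  representation(entries = "data.frame", bestK = "integer",
                 clusterScores = "matrix"))

setValidity("EdgeScoreTable", function(object) {
  e <- object@entries
  if (!all(c("regulator", "target", "score") %in% names(e)))
    return("entries needs regulator, target, score columns")
  if (nrow(e)) {
    a <- abs(e$score)
    if (any(diff(a) > 1e-12)) return("entries must be sorted by descending |score|")
    if (any(e$regulator == e$target)) return("self-edges are not allowed")
  }
  TRUE
})

#' AUROC/AUPR evaluation of a ranked edge list
#'
#' @slot auroc area under the receiver operating characteristic curve.
#' @slot aupr area under the precision-recall curve (step-wise, no
#'   interpolation across recall gaps).
#' @slot nTrue number of gold-standard true edges.
#' @slot nCandidates number of candidate edges scored.
#' @slot rocPoints data.frame(fpr, tpr).
#' @slot prPoints data.frame(recall, precision).
#' @export
setClass("EvalResult",
  representation(auroc = "numeric", aupr = "numeric", nTrue = "integer",
                 nCandidates = "integer", rocPoints = "data.frame",
                 prPoints = "data.frame"))

#' Specification for the generative simulator
#'
#' @slot K,G,T,nSeries,nReplicates problem dimensions.
#' @slot edgeDensity probability of a nonzero off-diagonal transition entry.
#' @slot coeffMagnitude absolute value of nonzero off-diagonal entries before
#'   stability rescaling.
#' @slot trendScale standard deviation of the per-cluster linear trend term.
#' @slot stateNoiseSd,obsNoiseSd process and measurement noise standard
#'   deviations.
#' @slot spectralCap stability bound on the spectral radius of the
#'   transition matrix.
#' @slot diagRange range of the positively biased diagonal (persistence)
#'   entries.
#' @slot seed integer seed.
#' @export
setClass("SimSpec",
  representation(K = "integer", G = "integer", T = "integer",
                 nSeries = "integer", nReplicates = "integer",
                 edgeDensity = "numeric", coeffMagnitude = "numeric",
                 trendScale = "numeric", stateNoiseSd = "numeric",
                 obsNoiseSd = "numeric", spectralCap = "numeric",
                 diagRange = "numeric", seed = "integer"))

setValidity("SimSpec", function(object) {
  msgs <- character()
  if (object@K > object@G) msgs <- c(msgs, "K must be <= G")
  if (object@T < 2L) msgs <- c(msgs, "need at least 2 time points")
  if (object@edgeDensity <= 0 || object@edgeDensity > 1)
    msgs <- c(msgs, "edgeDensity must be in (0, 1]")
  if (object@spectralCap <= 0 || object@spectralCap >= 1)
    msgs <- c(msgs, "spectralCap must be in (0, 1)")
  if (object@stateNoiseSd <= 0 || object@obsNoiseSd <= 0)
    msgs <- c(msgs, "noise standard deviations must be > 0")
  if (object@trendScale < 0) msgs <- c(msgs, "trendScale must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' True parameters behind a simulated data set
#'
#' @slot K,G dimensions.
#' @slot B K x K transition matrix; row k holds the coefficients feeding
#'   cluster k at time t+1 (entry (k, j) is the influence of cluster j).
#' @slot d length-K trend vector.
#' @slot z length-G cluster memberships.
#' @slot rho per-cluster state-noise precision.
#' @slot tau observation precision.
#' @slot initStatePrec precision of the initial state draw.
#' @export
setClass("GenerativeParams",
  representation(K = "integer", G = "integer", B = "matrix", d = "numeric",
                 z = "integer", rho = "numeric", tau = "numeric",
                 initStatePrec = "numeric"))
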