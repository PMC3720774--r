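#' Simulator specification constructor
#'
#' Defaults mirror the shape of the DREAM4 10-gene time-series benchmark
#' (10 genes, 20 time points, 5 series, no technical replicates) with 3
#' underlying clusters and a signal-to-noise ratio of roughly ten between
#' the unit-scale cluster trajectories and the measurement noise.
#'
#' @param K number of clusters.
#' @param G number of genes.
#' @param T number of time points per series.
#' @param nSeries number of independent series.
#' @param nReplicates technical replicates per series (default 1).
#' @param edgeDensity probability that an off-diagonal transition entry is
#'   nonzero (default 0.3).
#' @param coeffMagnitude absolute value of nonzero off-diagonal entries
#'   before stability rescaling (default 0.8).
#' @param trendScale standard deviation of the per-cluster trend term
#'   (default 0.3).
#' @param stateNoiseSd process noise standard deviation (default 0.3).
#' @param obsNoiseSd measurement noise standard deviation (default 0.3).
#' @param spectralCap stability bound on the spectral radius of the
#'   transition matrix (default 0.9).
#' @param diagRange range of the positively biased diagonal (persistence)
#'   entries (default c(0.2, 0.6)).
#' @param seed integer seed.
#' @return A \linkS4class{SimSpec}.
#' @export
simSpec <- function(K = 3L, G = 10L, T = 20L, nSeries = 5L,
                    nReplicates = 1L, edgeDensity = 0.3,
                    coeffMagnitude = 0.8, trendScale = 0.3,
                    stateNoiseSd = 0.3, obsNoiseSd = 0.3,
                    spectralCap = 0.9, diagRange = c(0.2, 0.6),
                    seed = 1L) {
  new("SimSpec", K = as.integer(K), G = as.integer(G), T = as.integer(T),
      nSeries = as.integer(nSeries), nReplicates = as.integer(nReplicates),
      edgeDensity = edgeDensity, coeffMagnitude = coeffMagnitude,
      trendScale = trendScale, stateNoiseSd = stateNoiseSd,
      obsNoiseSd = obsNoiseSd, spectralCap = spectralCap,
      diagRange = as.numeric(diagRange), seed = as.integer(seed))
}

#' Simulate a clustered network and its time-course data
#'
#' Draws the generative model the estimator assumes: a sparse K x K
#' transition matrix with positively biased diagonal (persistence) and
#' off-diagonal entries of magnitude `coeffMagnitude` at density
#' `edgeDensity`, rescaled so its spectral radius does not exceed
#' `spectralCap`; a Gaussian trend vector; round-robin (then shuffled)
#' cluster memberships so every cluster is non-empty; latent cluster
#' trajectories started at standard normal draws and propagated through
#' the dynamics with Gaussian process noise; and observed gene series
#' equal to their cluster's trajectory plus measurement noise. The gold
#' standard contains every ordered pair of distinct genes whose cluster
#' pair has a nonzero transition coefficient.
#'
#' @param spec a \linkS4class{SimSpec}.
#' @return list(data = \linkS4class{TimeSeriesSet},
#'   params = \linkS4class{GenerativeParams},
#'   gold = \linkS4class{GoldStandard}).
#' @export
simulateNetwork <- function(spec) {
  validObject(spec)
  K <- spec@K; G <- spec@G; T <- spec@T
  withSeed(spec@seed, {
    B <- matrix(0, K, K)
    diag(B) <- runif(K, spec@diagRange[1L], spec@diagRange[2L])
    off <- which(row(B) != col(B))
    hit <- off[runif(length(off)) < spec@edgeDensity]
    B[hit] <- spec@coeffMagnitude * sample(c(-1, 1), length(hit),
                                           replace = TRUE)
    ok <- FALSE
    for (attempt in seq_len(100L)) {
      r <- spectralRadius(B)
      if (r <= spec@spectralCap) { ok <- TRUE; break }
      B <- B * (spec@spectralCap / r)
    }
    if (!ok) stop("could not rescale the transition matrix to stability")
    d <- rnorm(K, 0, spec@trendScale)
    z <- integer(G)
    z[sample.int(G)] <- rep_len(seq_len(K), G)
    genes <- paste0("G", seq_len(G))
    seriesList <- vector("list", spec@nSeries)
    for (s in seq_len(spec@nSeries)) {
      X <- matrix(0, K, T)
      X[, 1L] <- rnorm(K)
      for (t in seq_len(T - 1L))
        X[, t + 1L] <- B %*% X[, t] + d + rnorm(K, 0, spec@stateNoiseSd)
      mats <- lapply(seq_len(spec@nReplicates), function(r)
        X[z, , drop = FALSE] + matrix(rnorm(G * T, 0, spec@obsNoiseSd), G, T))
      seriesList[[s]] <- ExpressionSeries(
        mats[[1L]], geneNames = genes, timePoints = seq_len(T) - 1,
        replicates = mats[-1L])
    }
    # gene-level true edges: pairs whose cluster pair interacts.
    # B[k, j] != 0 means cluster j drives cluster k, so gene u (in cluster
    # z_u) regulates gene v when B[z_v, z_u] is nonzero.
    reg <- rep(seq_len(G), each = G)
    tgt <- rep(seq_len(G), times = G)
    keep <- reg != tgt & B[cbind(z[tgt], z[reg])] != 0
    gold <- GoldStandard(cbind(genes[reg[keep]], genes[tgt[keep]]), genes)
    params <- new("GenerativeParams", K = K, G = G, B = B, d = d, z = z,
                  rho = rep(1 / spec@stateNoiseSd^2, K),
                  tau = 1 / spec@obsNoiseSd^2, initStatePrec = 1)
    list(data = TimeSeriesSet(seriesList, networkId = "simulated"),
         params = params, gold = gold)
  })
}

#' Mutually uncorrelated persistent profiles
#'
#' Generates the no-cluster-structure reference condition: every gene is
#' its own cluster and follows an independent, strongly persistent AR(1)
#' trajectory (no cross-regulation, no trend), redrawn independently in
#' every series, observed with low measurement noise. Because each series
#' carries its own independent trajectories, gene profiles are
#' uncorrelated in expectation and, pooled across series, nearly
#' uncorrelated in sample — the regime in which model selection should
#' retain one cluster per gene rather than merge genes.
#'
#' @param G number of genes (= clusters).
#' @param T time points per series.
#' @param nSeries number of series.
#' @param persistence range of the AR(1) diagonal (default c(0.85, 0.95)).
#' @param stateNoiseSd innovation standard deviation (default 0.3).
#' @param obsNoiseSd measurement noise standard deviation (default 0.2).
#' @param seed integer seed.
#' @return list(data, params, gold) as in [simulateNetwork()]; the gold
#'   standard is empty (there is no cross-regulation).
#' @export
uncorrelatedProfiles <- function(G = 10L, T = 20L, nSeries = 5L,
                                 persistence = c(0.85, 0.95),
                                 stateNoiseSd = 0.3, obsNoiseSd = 0.2,
                                 seed = 1L) {
  simulateNetwork(simSpec(K = G, G = G, T = T, nSeries = nSeries,
                          edgeDensity = .Machine$double.eps,
                          trendScale = 0, diagRange = persistence,
                          stateNoiseSd = stateNoiseSd,
                          obsNoiseSd = obsNoiseSd, seed = seed))
}

#' DREAM4-shaped synthetic fixture
#'
#' Generates a fixture with the exact shape of one DREAM4 10-gene
#' time-series data set: 10 genes, 20 time points, 5 series, no technical
#' replicates. Optionally writes the series table and gold standard in the
#' package's TSV dialects.
#'
#' @param seed integer seed.
#' @param dir optional directory; when given, writes `series.tsv` and
#'   `gold.tsv` there.
#' @return list(data, params, gold), invisibly carrying the written paths
#'   as attribute `paths` when `dir` is set.
#' @export
dream4Fixture <- function(seed = 1L, dir = NULL) {
  out <- simulateNetwork(simSpec(K = 3L, G = 10L, T = 20L, nSeries = 5L,
                                 nReplicates = 1L, seed = seed))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    sPath <- file.path(dir, "series.tsv")
    gPath <- file.path(dir, "gold.tsv")
    writeTimeSeries(out$data, sPath)
    e <- out$gold@edges
    writeLines(paste(e[, 1L], e[, 2L], "1", sep = "\t"), gPath)
    attr(out, "paths") <- c(series = sPath, gold = gPath)
  }
  out
}
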