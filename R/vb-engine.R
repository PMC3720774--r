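# Coordinate-ascent variational Bayes for the clustered dynamic network
# model. The latent cluster expressions x_t (length K, one chain per
# series) follow linear dynamics x_{t+1} = B x_t + d + eta with diagonal
# state-noise precision rho, each observed gene equals its cluster's
# expression plus measurement noise of per-series precision tau, and each
# gene carries a one-hot cluster membership with a uniform prior. The
# posterior factorises over per-series state trajectories (each kept as a
# joint Gaussian chain, i.e. a structured/smoother factor with first-lag
# cross-covariances), augmented transition rows (B_j, d_j), memberships,
# and the gamma precisions; the ARD prior precisions on B, d and the
# initial state are point-estimated by evidence maximisation. Every
# update below is the exact optimal factor given the others, so the
# evidence lower bound is non-decreasing.

# ---- data preparation --------------------------------------------------

# Standardise each gene within each series (pooled over replicates) and
# precompute the per-series sufficient statistics the updates reuse.
.prep <- function(data, config) {
  stopifnot(is(data, "TimeSeriesSet"))
  genes <- geneNames(data)
  G <- length(genes)
  S <- length(data@series)
  Tn <- integer(S); Rn <- integer(S)
  Ysum <- vector("list", S); sumYsq <- vector("list", S)
  for (s in seq_len(S)) {
    es <- data@series[[s]]
    mats <- c(list(es@values), es@replicates)
    Tn[s] <- ncol(es@values)
    Rn[s] <- length(mats)
    if (config@standardize) {
      all <- do.call(cbind, mats)
      ctr <- rowMeans(all)
      scl <- apply(all, 1L, stats::sd)
      scl[!is.finite(scl) | scl < 1e-12] <- 1
      mats <- lapply(mats, function(m) (m - ctr) / scl)
    }
    Ysum[[s]] <- Reduce(`+`, mats)
    sumYsq[[s]] <- Reduce(`+`, lapply(mats, function(m) rowSums(m^2)))
  }
  list(G = G, S = S, K = config@K, genes = genes, Tn = Tn, Rn = Rn,
       Ysum = Ysum, sumYsq = sumYsq, config = config)
}

# ---- moments and sufficient statistics ---------------------------------

.rowMoments <- function(qB) {
  K <- nrow(qB$mean)
  lapply(seq_len(K), function(j)
    tcrossprod(qB$mean[j, ]) + qB$cov[[j]])
}

# Per-series state statistics over the T-1 transitions:
#   Sw  = sum_t E[w_t w_t'] with w_t = (x_t, 1)
#   Cx  = (K+1) x K, column j = sum_t E[x_{j,t+1} w_t] (uses the chain's
#         first-lag cross-covariances C_t = Cov(x_t, x_{t+1}))
#   XX2 = sum_{t=2..T} E[x_{j,t}^2]  (per cluster j)
.seriesStats <- function(qXs) {
  M <- qXs$M; Slist <- qXs$S; Clist <- qXs$C
  K <- nrow(M); T <- ncol(M)
  Sw <- matrix(0, K + 1L, K + 1L)
  Cx <- matrix(0, K + 1L, K)
  XX2 <- numeric(K)
  for (t in seq_len(T - 1L)) {
    mt <- M[, t]
    Ewt <- c(mt, 1)
    Eww <- rbind(cbind(Slist[[t]] + tcrossprod(mt), mt), c(mt, 1))
    Sw <- Sw + Eww
    Cx <- Cx + outer(Ewt, M[, t + 1L]) +
      rbind(Clist[[t]], 0)
    XX2 <- XX2 + M[, t + 1L]^2 + diag(Slist[[t + 1L]])
  }
  list(Sw = Sw, Cx = Cx, XX2 = XX2)
}

.eTau <- function(st) st$qTau[, 1L] / st$qTau[, 2L]
.eRho <- function(st, s) st$qRho[[s]][, 1L] / st$qRho[[s]][, 2L]

# D[i, k] = sum_{t, r} E[(y_{i,t,r} - x_{k,t})^2] for one series.
.obsDist <- function(st, prep, s) {
  M <- st$qX[[s]]$M
  Sdiag <- vapply(st$qX[[s]]$S, diag, numeric(prep$K))
  if (prep$K == 1L) Sdiag <- matrix(Sdiag, nrow = 1L)
  msq <- rowSums(M^2) + rowSums(Sdiag)
  D <- prep$sumYsq[[s]] - 2 * prep$Ysum[[s]] %*% t(M) +
    prep$Rn[s] * matrix(msq, prep$G, prep$K, byrow = TRUE)
  D
}

# ---- factor updates ----------------------------------------------------

# Exact structured update of one series' state chain: the optimal factor
# q(x_{1:T}) is a Gaussian with block-tridiagonal precision, solved by
# forward block elimination and backward substitution (the information-
# form Rauch-Tung-Striebel smoother). Returns marginal means/covariances,
# first-lag cross-covariances Cov(x_t, x_{t+1}), and the joint entropy.
.vbStates <- function(st, prep) {
  K <- prep$K
  EB <- st$qB$mean[, seq_len(K), drop = FALSE]    # row j = B_j
  Ed <- st$qB$mean[, K + 1L]
  rowM <- .rowMoments(st$qB)
  Etau <- .eTau(st)
  for (s in seq_len(prep$S)) {
    Erho <- .eRho(st, s)
    # quadratic pieces of E[log p(x_{t+1} | x_t)]:
    #   A    = E[B' diag(rho) B]   (precision carried onto x_t)
    #   crho = E[B' diag(rho) d]   (linear term onto x_t)
    #   O    = -E[B]' diag(rho)    ... off-diagonal block -diag(rho) E[B]
    A <- matrix(0, K, K)
    crho <- numeric(K)
    for (j in seq_len(K)) {
      A <- A + Erho[j] * rowM[[j]][seq_len(K), seq_len(K)]
      crho <- crho + Erho[j] * rowM[[j]][seq_len(K), K + 1L]
    }
    O <- -t(EB * Erho)                             # J_{t,t+1} block
    rZ <- prep$Rn[s] * colSums(st$qZ)              # per-cluster obs mass
    obsPrec <- Etau[s] * rZ
    obsH <- Etau[s] * crossprod(st$qZ, prep$Ysum[[s]])  # K x T
    T <- prep$Tn[s]
    rhoEd <- Erho * Ed
    Dbar <- vector("list", T)
    hbar <- vector("list", T)
    logdetJ <- 0
    for (t in seq_len(T)) {
      D <- diag(obsPrec + (if (t == 1L) st$ard$x0 else Erho), K)
      if (t < T) D <- D + A
      h <- obsH[, t]
      if (t > 1L) h <- h + rhoEd
      if (t < T) h <- h - crho
      if (t > 1L) {
        # eliminate x_{t-1}: D - O' Dbar^{-1} O, h - O' Dbar^{-1} hbar
        W <- backsolve(Ut, forwardsolve(t(Ut), O))  # Dbar_{t-1}^{-1} O
        D <- D - crossprod(O, W)
        h <- h - crossprod(W, hbar[[t - 1L]])
      }
      Ut <- chol(symm(D))
      logdetJ <- logdetJ + 2 * sum(log(diag(Ut)))
      Dbar[[t]] <- Ut                               # store the factor
      hbar[[t]] <- h
    }
    M <- matrix(0, K, T)
    Slist <- vector("list", T)
    Clist <- vector("list", max(T - 1L, 0L))
    Ut <- Dbar[[T]]
    M[, T] <- backsolve(Ut, forwardsolve(t(Ut), hbar[[T]]))
    Slist[[T]] <- symm(chol2inv(Ut))
    for (t in seq.int(T - 1L, 1L)) {
      Ut <- Dbar[[t]]
      W <- backsolve(Ut, forwardsolve(t(Ut), O))    # Dbar_t^{-1} O
      M[, t] <- backsolve(Ut, forwardsolve(t(Ut), hbar[[t]])) -
        W %*% M[, t + 1L]
      Slist[[t]] <- symm(chol2inv(Ut) + W %*% Slist[[t + 1L]] %*% t(W))
      Clist[[t]] <- -W %*% Slist[[t + 1L]]          # Cov(x_t, x_{t+1})
    }
    H <- 0.5 * (K * T * (1 + log(2 * pi)) - logdetJ)
    st$qX[[s]] <- list(M = M, S = Slist, C = Clist, H = H)
  }
  st
}

.vbDynamics <- function(st, prep, stats = NULL) {
  K <- prep$K
  if (is.null(stats)) stats <- lapply(st$qX, .seriesStats)
  mean <- st$qB$mean
  cov <- st$qB$cov
  for (j in seq_len(K)) {
    Prec <- diag(c(st$ard$B[j, ], st$ard$d[j]), K + 1L)
    rhs <- numeric(K + 1L)
    for (s in seq_len(prep$S)) {
      Erho <- .eRho(st, s)
      Prec <- Prec + Erho[j] * stats[[s]]$Sw
      rhs <- rhs + Erho[j] * stats[[s]]$Cx[, j]
    }
    V <- chol2inv(chol(symm(Prec)))
    mean[j, ] <- V %*% rhs
    cov[[j]] <- symm(V)
  }
  st$qB <- list(mean = mean, cov = cov)
  st
}

.vbMemberships <- function(st, prep, D = NULL) {
  if (!is.null(prep$config@clampMemberships)) return(st)
  Etau <- .eTau(st)
  logits <- matrix(0, prep$G, prep$K)
  for (s in seq_len(prep$S))
    logits <- logits - 0.5 * Etau[s] *
      (if (is.null(D)) .obsDist(st, prep, s) else D[[s]])
  st$qZ <- softmaxRows(logits)
  st
}

.vbPrecisions <- function(st, prep, stats = NULL, Dall = NULL) {
  a0 <- st$ard$gamma[1L]; b0 <- st$ard$gamma[2L]
  if (is.null(stats)) stats <- lapply(st$qX, .seriesStats)
  rowM <- .rowMoments(st$qB)
  for (s in seq_len(prep$S)) {
    D <- if (is.null(Dall)) .obsDist(st, prep, s) else Dall[[s]]
    sse <- sum(st$qZ * D)
    nObs <- prep$G * prep$Tn[s] * prep$Rn[s]
    st$qTau[s, ] <- c(a0 + nObs / 2, b0 + max(sse, 0) / 2)
    res <- .expectedResiduals(st, stats[[s]], rowM)
    st$qRho[[s]] <- cbind(a0 + (prep$Tn[s] - 1L) / 2, b0 + pmax(res, 0) / 2)
  }
  st
}

# E[sum_t (x_{j,t+1} - B_j x_t - d_j)^2] per cluster row j for one series.
.expectedResiduals <- function(st, sstats, rowM = .rowMoments(st$qB)) {
  K <- nrow(st$qB$mean)
  vapply(seq_len(K), function(j) {
    sstats$XX2[j] - 2 * sum(st$qB$mean[j, ] * sstats$Cx[, j]) +
      sum(rowM[[j]] * sstats$Sw)
  }, 1)
}

.vbHyper <- function(st, prep) {
  lo <- prep$config@ardBounds[1L]; hi <- prep$config@ardBounds[2L]
  clip <- function(x) pmin(pmax(x, lo), hi)
  K <- prep$K
  rowM <- .rowMoments(st$qB)
  for (j in seq_len(K)) {
    sec <- diag(rowM[[j]])
    st$ard$B[j, ] <- clip(1 / sec[seq_len(K)])
    st$ard$d[j] <- clip(1 / sec[K + 1L])
  }
  x0sq <- numeric(K)
  for (s in seq_len(prep$S))
    x0sq <- x0sq + st$qX[[s]]$M[, 1L]^2 + diag(st$qX[[s]]$S[[1L]])
  st$ard$x0 <- clip(prep$S / x0sq)
  # shared gamma hyperprior over all precision variables (tau and rho),
  # re-estimated by evidence maximisation: with S1 = mean E[log gamma_i]
  # and S2 = mean E[gamma_i], the profiled optimum solves
  # log(a0) - digamma(a0) = log(S2) - S1, b0 = a0 / S2.
  Es <- .eTau(st)
  Els <- gammaElog(st$qTau[, 1L], st$qTau[, 2L])
  for (s in seq_len(prep$S)) {
    Es <- c(Es, .eRho(st, s))
    Els <- c(Els, gammaElog(st$qRho[[s]][, 1L], st$qRho[[s]][, 2L]))
  }
  cand <- .gammaHyperOpt(mean(Els), mean(Es), lo, hi)
  obj <- function(ab) ab[1L] * log(ab[2L]) - lgamma(ab[1L]) +
    (ab[1L] - 1) * mean(Els) - ab[2L] * mean(Es)
  # bound clipping can make the closed-form candidate suboptimal; never
  # accept a hyperparameter move that lowers the bound
  if (obj(cand) > obj(st$ard$gamma)) st$ard$gamma <- cand
  st
}

# Maximise n * (a log b - lgamma(a) + (a - 1) S1 - b S2) over (a, b).
.gammaHyperOpt <- function(S1, S2, lo = 1e-6, hi = 1e6) {
  gap <- log(S2) - S1                      # >= 0 by Jensen's inequality
  f <- function(la) {
    a <- exp(la)
    log(a) - digamma(a) - gap
  }
  a <- if (!is.finite(gap) || gap <= f(log(hi)) || gap < 1e-12) hi
  else if (gap >= f(log(lo))) lo
  else exp(stats::uniroot(f, c(log(lo), log(hi)), tol = 1e-10)$root)
  a <- min(max(a, lo), hi)
  b <- min(max(a / S2, lo), hi)
  c(a, b)
}

# ---- evidence lower bound ----------------------------------------------

.vbELBO <- function(st, prep, stats = NULL, Dall = NULL) {
  K <- prep$K
  a0 <- st$ard$gamma[1L]; b0 <- st$ard$gamma[2L]
  l2p <- log(2 * pi)
  if (is.null(stats)) stats <- lapply(st$qX, .seriesStats)
  rowM <- .rowMoments(st$qB)
  elbo <- 0
  gammaPrior <- function(shape, rate) {
    a0 * log(b0) - lgamma(a0) + (a0 - 1) * gammaElog(shape, rate) -
      b0 * shape / rate
  }
  for (s in seq_len(prep$S)) {
    # observation likelihood
    D <- if (is.null(Dall)) .obsDist(st, prep, s) else Dall[[s]]
    sse <- sum(st$qZ * D)
    nObs <- prep$G * prep$Tn[s] * prep$Rn[s]
    elbo <- elbo + (nObs / 2) * (gammaElog(st$qTau[s, 1L], st$qTau[s, 2L]) -
                                   l2p) -
      (.eTau(st)[s] / 2) * sse
    # dynamics likelihood
    res <- .expectedResiduals(st, stats[[s]], rowM)
    Erho <- .eRho(st, s)
    Elrho <- gammaElog(st$qRho[[s]][, 1L], st$qRho[[s]][, 2L])
    elbo <- elbo + sum(((prep$Tn[s] - 1L) / 2) * (Elrho - l2p) -
                         (Erho / 2) * res)
    # initial state prior
    x0sq <- st$qX[[s]]$M[, 1L]^2 + diag(st$qX[[s]]$S[[1L]])
    elbo <- elbo + 0.5 * sum(log(st$ard$x0) - l2p - st$ard$x0 * x0sq)
    # gamma priors and entropies of the precisions
    elbo <- elbo + gammaPrior(st$qTau[s, 1L], st$qTau[s, 2L]) +
      gammaEntropy(st$qTau[s, 1L], st$qTau[s, 2L])
    elbo <- elbo + sum(gammaPrior(st$qRho[[s]][, 1L], st$qRho[[s]][, 2L])) +
      sum(gammaEntropy(st$qRho[[s]][, 1L], st$qRho[[s]][, 2L]))
    # joint entropy of the state chain
    elbo <- elbo + st$qX[[s]]$H
  }
  # transition-row priors and entropies
  for (j in seq_len(K)) {
    sec <- diag(rowM[[j]])
    prec <- c(st$ard$B[j, ], st$ard$d[j])
    elbo <- elbo + 0.5 * sum(log(prec) - l2p - prec * sec)
    elbo <- elbo + gaussianEntropy(st$qB$cov[[j]])
  }
  # memberships: uniform prior and entropy
  elbo <- elbo - prep$G * log(K)
  rz <- st$qZ[st$qZ > 0]
  elbo <- elbo - sum(rz * log(rz))
  elbo
}

# ---- initialisation ----------------------------------------------------

.vbInit <- function(prep, config) {
  K <- config@K; G <- prep$G
  if (K > G) stop("more clusters than genes (K > G)")
  clamp <- config@clampMemberships
  if (!is.null(clamp) && length(clamp) != G)
    stop("clampMemberships must have one entry per gene")
  withSeed(config@seed, {
    if (is.null(clamp)) {
      grp <- integer(G)
      grp[sample.int(G)] <- rep_len(seq_len(K), G)
    } else grp <- clamp
    qX <- vector("list", prep$S)
    for (s in seq_len(prep$S)) {
      T <- prep$Tn[s]
      M <- matrix(0, K, T)
      for (k in seq_len(K)) {
        sel <- which(grp == k)
        if (length(sel))
          M[k, ] <- colMeans(prep$Ysum[[s]][sel, , drop = FALSE] /
                               prep$Rn[s])
      }
      M <- M + matrix(rnorm(K * T, 0, 0.05), K, T)
      S0 <- diag(0.01, K)
      qX[[s]] <- list(M = M, S = rep(list(S0), T),
                      C = rep(list(matrix(0, K, K)), T - 1L),
                      H = T * gaussianEntropy(S0))
    }
    # responsibilities start at the seeded partition (one-hot): a uniform
    # start makes the observation message identical for every cluster and
    # leaves the fit on a label-symmetric ridge it can only leave through
    # round-off, so clusters never separate reliably
    qZ <- {
      z <- matrix(0, G, K); z[cbind(seq_len(G), grp)] <- 1; z
    }
    list(
      qB = list(mean = matrix(0, K, K + 1L),
                cov = rep(list(diag(1 / config@ardInit, K + 1L)), K)),
      qX = qX, qZ = qZ,
      qTau = matrix(rep(c(config@a0, config@b0), each = prep$S), prep$S, 2L),
      qRho = rep(list(matrix(rep(c(config@a0, config@b0), each = K), K, 2L)),
                 prep$S),
      ard = list(B = matrix(config@ardInit, K, K),
                 d = rep(config@ardInit, K), x0 = rep(config@ardInit, K),
                 gamma = c(config@a0, config@b0)))
  })
}

# ---- S4 wrappers -------------------------------------------------------

.toFit <- function(st, prep, config, converged = FALSE, nSweeps = 0L,
                   trace = numeric()) {
  new("BaconFit", qB = st$qB, qX = st$qX, qZ = st$qZ, qTau = st$qTau,
      qRho = st$qRho, ard = st$ard, elboTrace = trace,
      converged = converged, nSweeps = as.integer(nSweeps),
      geneNames = prep$genes, config = config)
}

.fromFit <- function(state) {
  list(qB = state@qB, qX = state@qX, qZ = state@qZ, qTau = state@qTau,
       qRho = state@qRho, ard = state@ard)
}

#' Model configuration constructor
#'
#' @param K number of clusters (at least 1, at most the number of genes).
#' @param maxSweeps maximum coordinate-ascent sweeps (default 2000).
#' @param relTol convergence threshold on the relative change of the
#'   evidence lower bound (default 1e-6).
#' @param seed integer seed for the randomised initialisation.
#' @param a0,b0 initial gamma hyperprior shape and rate shared by all
#'   precision parameters (default 1e-3, a broad start; both are
#'   re-estimated by evidence maximisation during the fit).
#' @param ardInit initial ARD prior precision (default 1).
#' @param ardBounds clip range for evidence-maximised ARD precisions.
#' @param clampMemberships optional fixed cluster index per gene; use
#'   `seq_len(G)` with `K = G` for the no-clustering mode.
#' @param standardize standardise genes within series before fitting
#'   (default TRUE; the observation model assumes comparable scales).
#' @return A \linkS4class{BaconConfig}.
#' @export
baconConfig <- function(K, maxSweeps = 2000L, relTol = 1e-6, seed = 1L,
                        a0 = 1e-3, b0 = 1e-3, ardInit = 1,
                        ardBounds = c(1e-6, 1e6), clampMemberships = NULL,
                        standardize = TRUE) {
  if (!is.null(clampMemberships))
    clampMemberships <- as.integer(clampMemberships)
  new("BaconConfig", K = as.integer(K), maxSweeps = as.integer(maxSweeps),
      relTol = relTol, seed = as.integer(seed), a0 = a0, b0 = b0,
      ardInit = ardInit, ardBounds = as.numeric(ardBounds),
      clampMemberships = clampMemberships, standardize = standardize)
}

#' Initialise the variational posterior
#'
#' Builds the starting posterior for a fit: a seeded random partition of
#' the genes provides both the one-hot starting responsibilities and the
#' initial state means (the partition centroids of the standardised gene
#' series, plus small jitter); transition rows start zero-mean at their
#' prior and gamma posteriors equal their priors. Deterministic given the
#' configuration seed.
#'
#' @param data a \linkS4class{TimeSeriesSet}.
#' @param config a \linkS4class{BaconConfig}.
#' @return A \linkS4class{BaconFit} with an empty ELBO trace.
#' @export
initPosterior <- function(data, config) {
  prep <- .prep(data, config)
  st <- .vbInit(prep, config)
  .toFit(st, prep, config)
}

.applyUpdate <- function(state, data, fun) {
  prep <- .prep(data, state@config)
  st <- fun(.fromFit(state), prep)
  .toFit(st, prep, state@config, state@converged, state@nSweeps,
         state@elboTrace)
}

#' Single coordinate-ascent updates
#'
#' Each function performs one block update of the mean-field posterior and
#' returns the new state; the evidence lower bound never decreases.
#' `updateStates` refreshes each series' joint Gaussian state chain,
#' combining the dynamics potentials between consecutive time points with
#' the responsibility-weighted observation evidence. `updateDynamics`
#' refreshes the Gaussian posterior of every augmented transition row
#' (B_j, d_j), pooling transitions from all series. `updateMemberships`
#' refreshes the responsibilities (no-op when clamped).
#' `updatePrecisions` refreshes the gamma posteriors of the observation
#' and state-noise precisions. `updateHyperparameters` re-estimates the
#' ARD prior precisions as the reciprocal posterior second moments
#' (clipped to the configured bounds) and the shared gamma hyperprior of
#' the precisions by marginal-likelihood maximisation.
#'
#' @param state a \linkS4class{BaconFit}.
#' @param data the \linkS4class{TimeSeriesSet} the state was built from.
#' @return The updated \linkS4class{BaconFit}.
#' @name updates
NULL

#' @rdname updates
#' @export
updateStates <- function(state, data) .applyUpdate(state, data, .vbStates)

#' @rdname updates
#' @export
updateDynamics <- function(state, data) .applyUpdate(state, data, .vbDynamics)

#' @rdname updates
#' @export
updateMemberships <- function(state, data)
  .applyUpdate(state, data, .vbMemberships)

#' @rdname updates
#' @export
updatePrecisions <- function(state, data)
  .applyUpdate(state, data, .vbPrecisions)

#' @rdname updates
#' @export
updateHyperparameters <- function(state, data) {
  prep <- .prep(data, state@config)
  st <- .vbHyper(.fromFit(state), prep)
  .toFit(st, prep, state@config, state@converged, state@nSweeps,
         state@elboTrace)
}

#' Evidence lower bound of a posterior state
#'
#' Computes E_q[log p(data, parameters)] - E_q[log q], the variational
#' lower bound on the log marginal likelihood used both as the convergence
#' criterion and for model selection across cluster counts.
#'
#' @param state a \linkS4class{BaconFit}.
#' @param data the \linkS4class{TimeSeriesSet} the state was built from.
#' @return A single numeric value.
#' @export
computeELBO <- function(state, data) {
  prep <- .prep(data, state@config)
  .vbELBO(.fromFit(state), prep)
}
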