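.checkFiniteFactor <- function(st, factor) {
  ok <- switch(factor,
    states = all(vapply(st$qX, function(q) all(is.finite(q$M)), TRUE)),
    dynamics = all(is.finite(st$qB$mean)),
    memberships = all(is.finite(st$qZ)),
    precisions = all(is.finite(st$qTau)) &&
      all(vapply(st$qRho, function(r) all(is.finite(r)), TRUE)),
    hyperparameters = all(is.finite(unlist(st$ard))),
    TRUE)
  if (!ok)
    stop(errorCondition(
      paste0("non-finite values after the '", factor, "' update"),
      class = c("baconetNumericalError", "error")))
  st
}

#' Fit the clustered dynamic network model
#'
#' Runs coordinate-ascent variational Bayes from a seeded random
#' initialisation: each sweep updates, in order, the cluster states, the
#' transition rows, the memberships, the precisions and the ARD
#' hyperparameters, then records the evidence lower bound. The fit stops
#' when the relative ELBO change drops below `config@relTol` or after
#' `config@maxSweeps` sweeps. Deterministic given the configuration seed.
#'
#' @param data a \linkS4class{TimeSeriesSet}.
#' @param config a \linkS4class{BaconConfig}.
#' @return A converged \linkS4class{BaconFit} carrying the full ELBO trace.
#' @examples
#' sim <- simulateNetwork(simSpec(K = 2, G = 6, T = 10, nSeries = 1, seed = 1))
#' fit <- baconFit(sim$data, baconConfig(K = 2, seed = 1, maxSweeps = 50))
#' memberships(fit)
#' @export
baconFit <- function(data, config) {
  validObject(config)
  prep <- .prep(data, config)
  st <- .vbInit(prep, config)
  trace <- numeric(0)
  converged <- FALSE
  sweeps <- 0L
  while (sweeps < config@maxSweeps) {
    st <- .checkFiniteFactor(.vbStates(st, prep), "states")
    # state sufficient statistics are reused by every later update in the
    # sweep (they depend on q(x) and the data only)
    sstats <- lapply(st$qX, .seriesStats)
    Dall <- lapply(seq_len(prep$S), function(s) .obsDist(st, prep, s))
    st <- .checkFiniteFactor(.vbDynamics(st, prep, sstats), "dynamics")
    st <- .checkFiniteFactor(.vbMemberships(st, prep, Dall), "memberships")
    st <- .checkFiniteFactor(.vbPrecisions(st, prep, sstats, Dall),
                             "precisions")
    st <- .checkFiniteFactor(.vbHyper(st, prep), "hyperparameters")
    elbo <- .vbELBO(st, prep, sstats, Dall)
    if (!is.finite(elbo))
      stop(errorCondition("non-finite evidence lower bound",
                          class = c("baconetNumericalError", "error")))
    sweeps <- sweeps + 1L
    trace <- c(trace, elbo)
    if (sweeps >= 2L) {
      prev <- trace[sweeps - 1L]
      if (abs(elbo - prev) < config@relTol * max(1, abs(prev))) {
        converged <- TRUE
        break
      }
    }
  }
  .toFit(st, prep, config, converged, sweeps, trace)
}
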