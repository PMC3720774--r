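#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm runif setNames sd
#' @importFrom utils packageVersion write.table head
NULL

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Row-wise log-sum-exp normalisation: returns exp(L - logsumexp(L)) by row.
softmaxRows <- function(L) {
  m <- apply(L, 1L, max)
  W <- exp(L - m)
  W / rowSums(W)
}

logSumExpRows <- function(L) {
  m <- apply(L, 1L, max)
  m + log(rowSums(exp(L - m)))
}

# Entropy of a multivariate normal with covariance S (via Cholesky).
gaussianEntropy <- function(S) {
  k <- nrow(S)
  0.5 * (k * (1 + log(2 * pi)) + 2 * sum(log(diag(chol(S)))))
}

# Entropy of Gamma(shape, rate).
gammaEntropy <- function(shape, rate) {
  shape - log(rate) + lgamma(shape) + (1 - shape) * digamma(shape)
}

# E[log X] for X ~ Gamma(shape, rate).
gammaElog <- function(shape, rate) digamma(shape) - log(rate)

# Symmetrise a nearly-symmetric matrix (guards accumulated round-off).
symm <- function(M) (M + t(M)) / 2

# Spectral radius (largest |eigenvalue|).
spectralRadius <- function(M) max(Mod(eigen(M, only.values = TRUE)$values))

# Deterministic per-(K, restart) seed derived from a base seed, kept within
# the 32-bit signed integer range expected by set.seed().
comboSeed <- function(baseSeed, K, restart) {
  s <- (as.double(baseSeed) %% 2147483647) * 2654435761 +
    K * 97561 + restart * 51329
  as.integer(s %% 2147483629) + 1L
}

# Locale-independent string ordering (C collation via radix sort).
cOrder <- function(...) order(..., method = "radix")

fmtNum <- function(x) trimws(formatC(x, digits = 6L, format = "g"))

stopData <- function(...) {
  stop(errorCondition(paste0(...), class = c("baconetDataError", "error")))
}
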