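# Independent oracles used by the tests. These deliberately avoid the
# package's own computational paths.

# Posterior of a 2-coefficient Gaussian linear model by dense numerical
# integration of prior x likelihood over a 2-D grid.
gridPosterior <- function(x, y, z, phi, mu0, Lambda0,
                          lim = 4, n = 401L) {
  T <- length(x)
  g <- seq(-lim, lim, length.out = n)
  B1 <- matrix(g, n, n)          # coefficient of x along rows
  B2 <- matrix(g, n, n, byrow = TRUE)
  d1 <- B1 - mu0[1L]; d2 <- B2 - mu0[2L]
  lp <- -0.5 * (Lambda0[1L, 1L] * d1^2 + 2 * Lambda0[1L, 2L] * d1 * d2 +
                  Lambda0[2L, 2L] * d2^2)
  for (t in seq_len(T - 1L))
    lp <- lp - 0.5 * phi * (z[t + 1L] - B1 * x[t] - B2 * y[t])^2
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  c(sum(B1 * p), sum(B2 * p))
}

# Conjugate Bayesian linear regression by sufficient-statistics
# accumulation (one observation at a time).
conjugateRegression <- function(X, y, phi, mu0, Lambda0) {
  P <- Lambda0
  h <- Lambda0 %*% mu0
  for (i in seq_along(y)) {
    w <- X[i, ]
    P <- P + phi * tcrossprod(w)
    h <- h + phi * y[i] * w
  }
  list(mean = as.numeric(solve(P, h)), precision = P)
}

# O(n^2) pairwise-concordance AUROC with half-credit for ties.
concordanceAUROC <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Adjusted Rand index from the contingency table (independent of mclust).
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sumij <- sum(choose(tab, 2))
  sumi <- sum(choose(rowSums(tab), 2))
  sumj <- sum(choose(colSums(tab), 2))
  expected <- sumi * sumj / choose(n, 2)
  maxidx <- (sumi + sumj) / 2
  if (maxidx == expected) return(1)
  (sumij - expected) / (maxidx - expected)
}

# Exact log-evidence of the collapsed linear-Gaussian model with known
# parameters (Kalman prediction-error decomposition).
kalmanLogLik <- function(Y, B, d, rho, tau, z, x0prec) {
  K <- nrow(B); T <- ncol(Y); G <- nrow(Y)
  H <- matrix(0, G, K); H[cbind(seq_len(G), z)] <- 1
  mu <- rep(0, K); P <- diag(1 / x0prec, K)
  ll <- 0
  for (t in seq_len(T)) {
    Sy <- H %*% P %*% t(H) + diag(1 / tau, G)
    r <- Y[, t] - H %*% mu
    ll <- ll - 0.5 * (G * log(2 * pi) +
                        as.numeric(determinant(Sy)$modulus) +
                        as.numeric(t(r) %*% solve(Sy, r)))
    Kg <- P %*% t(H) %*% solve(Sy)
    mu <- mu + Kg %*% r
    P <- P - Kg %*% H %*% P
    if (t < T) {
      mu <- B %*% mu + d
      P <- B %*% P %*% t(B) + diag(1 / rho, K)
    }
  }
  ll
}

# Small deterministic time-series set for unit tests.
toySeriesSet <- function(G = 4L, T = 6L, S = 2L, seed = 1L) {
  set.seed(seed)
  genes <- paste0("G", seq_len(G))
  TimeSeriesSet(lapply(seq_len(S), function(s)
    ExpressionSeries(matrix(rnorm(G * T), G, T), geneNames = genes)),
    networkId = "toy")
}

# Build an EdgeScoreTable directly from a (regulator, target, score)
# data.frame, sorting as the package contract requires.
edgeTable <- function(df, K = 1L) {
  df <- df[order(-abs(df$score), df$regulator, df$target,
                 method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  new("EdgeScoreTable", entries = df, bestK = as.integer(K),
      clusterScores = matrix(numeric(), 0L, 0L))
}

# Full candidate-pair table over a universe with given scores.
fullRanking <- function(genes, scores) {
  G <- length(genes)
  reg <- rep(seq_len(G), each = G)
  tgt <- rep(seq_len(G), times = G)
  keep <- reg != tgt
  edgeTable(data.frame(regulator = genes[reg[keep]],
                       target = genes[tgt[keep]],
                       score = scores, stringsAsFactors = FALSE))
}
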