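#' Closed-form posterior for a two-regulator linear model
#'
#' The analytically tractable special case that motivates clustering: a
#' target gene Z whose next-step expression is a noisy linear combination of
#' two candidate regulators X and Y,
#' \deqn{z_{t+1} = b_x x_t + b_y y_t + \epsilon, \quad
#'       \epsilon \sim N(0, \phi^{-1}),}
#' with a bivariate normal prior \eqn{(b_x, b_y) \sim N(\mu_0,
#' \Lambda_0^{-1})}. The posterior is multivariate normal with precision
#' \eqn{\Lambda_0 + \phi \sum_t w_t w_t^\top} and mean
#' \eqn{\Lambda^{-1}(\Lambda_0 \mu_0 + \phi \sum_t z_{t+1} w_t)}, where
#' \eqn{w_t = (x_t, y_t)^\top} and the sum runs over the T-1 transitions.
#' When X and Y are strongly correlated this precision matrix approaches
#' singularity and the posterior variances of both coefficients blow up —
#' the identifiability failure the clustering model is designed to avoid.
#'
#' @param x,y,z numeric vectors of equal length T >= 2: the observed series
#'   of the two candidate regulators and the target.
#' @param phi fixed noise precision (inverse variance) of the dynamics.
#' @param mu0 length-2 prior mean (default zero).
#' @param Lambda0 2 x 2 symmetric positive-definite prior precision.
#' @return list(mean = length-2 posterior mean, precision = 2 x 2 posterior
#'   precision, covariance = its inverse).
#' @examples
#' tt <- seq_len(10)
#' xs <- sin(tt); ys <- cos(tt); zs <- c(0, 0.8 * xs[-10] - 0.3 * ys[-10])
#' twoRegulatorPosterior(xs, ys, zs, phi = 4)
#' @export
twoRegulatorPosterior <- function(x, y, z, phi, mu0 = c(0, 0),
                                  Lambda0 = diag(2)) {
  stopifnot(length(x) == length(y), length(y) == length(z),
            phi >= 0, length(mu0) == 2L)
  Lambda0 <- as.matrix(Lambda0)
  if (!isTRUE(all.equal(Lambda0, t(Lambda0))) ||
      any(eigen(Lambda0, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("Lambda0 must be symmetric positive definite")
  T <- length(x)
  if (T < 2L) stop("need at least 2 time points (no transitions)")
  W <- cbind(x[-T], y[-T])              # w_t = (x_t, y_t), t = 1..T-1
  zNext <- z[-1L]
  precision <- symm(Lambda0 + phi * crossprod(W))
  rhs <- Lambda0 %*% mu0 + phi * crossprod(W, zNext)
  covariance <- symm(solve(precision))
  list(mean = as.numeric(covariance %*% rhs), precision = precision,
       covariance = covariance)
}

#' Posterior variance under increasingly correlated regressors
#'
#' Profiles the identifiability collapse of the two-regulator posterior:
#' for each correlation level r, the second regulator is a mixture
#' \eqn{y = r x + (1 - r) u} of the first regulator and independent noise,
#' rescaled to unit variance, and the posterior variance of the first
#' coefficient is computed. The variance is non-decreasing in r for fixed
#' prior precision and non-increasing in the prior precision for fixed r;
#' at r = 1 with a vanishing prior it diverges.
#'
#' @param r correlation levels, each in [0, 1].
#' @param eps scalar prior precision (prior is eps times the identity).
#' @param x the fixed regressor series; default a seeded smooth profile.
#' @param phi fixed noise precision.
#' @param seed seed for the independent noise component.
#' @return numeric vector of posterior variances of the first coefficient,
#'   one per element of `r`.
#' @export
singularityProfile <- function(r, eps = 1e-8,
                               x = sin(seq(0, 3 * pi, length.out = 20)),
                               phi = 1, seed = 1L) {
  if (any(r < 0 | r > 1)) stop("correlation levels must lie in [0, 1]")
  stopifnot(eps > 0)
  T <- length(x)
  u <- withSeed(seed, rnorm(T))
  # target plays no role in the posterior variance; use zeros
  zTarget <- numeric(T)
  vapply(r, function(ri) {
    y <- ri * x + (1 - ri) * u
    sdy <- stats::sd(y)
    if (sdy > 0) y <- y / sdy * stats::sd(x)
    post <- twoRegulatorPosterior(x, y, zTarget, phi = phi,
                                  Lambda0 = eps * diag(2))
    post$covariance[1L, 1L]
  }, 1)
}
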