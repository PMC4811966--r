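## Probability mass functions for the four count families, with the mixture
## structure written out explicitly. Linear predictors are clipped at +-30
## before exponentiation (an event counted by the caller where relevant) so
## that mixture masses stay finite under extreme predictors.

.CLIP <- 30

.clip_exp <- function(eta) exp(pmin(pmax(eta, -.CLIP), .CLIP))

.check_count <- function(y) {
  if (any(!is.finite(y)) || any(y < 0) || any(y != floor(y)))
    stop("y must be finite nonnegative integers")
}

#' Poisson log probability mass
#'
#' @param y Nonnegative integer count(s).
#' @param mu Positive mean(s).
#' @return `log P(Y = y)` under Poisson(mu).
#' @export
poisson_logpmf <- function(y, mu) {
  .check_count(y)
  if (any(mu <= 0)) stop("mu must be positive")
  stats::dpois(y, mu, log = TRUE)
}

#' Negative binomial log probability mass
#'
#' Mean/dispersion parameterization: `E(Y) = mu`, `Var(Y) = mu + mu^2/theta`.
#'
#' @param y Nonnegative integer count(s).
#' @param mu Positive mean(s).
#' @param theta Positive dispersion; the Poisson limit is `theta -> Inf`.
#' @return `log P(Y = y)`.
#' @export
negbin_logpmf <- function(y, mu, theta) {
  .check_count(y)
  if (any(mu <= 0)) stop("mu must be positive")
  if (any(theta <= 0)) stop("theta must be positive")
  stats::dnbinom(y, size = theta, mu = mu, log = TRUE)
}

#' Zero-inflated Poisson log probability mass
#'
#' A point mass at zero with probability `pi` mixed with Poisson(mu):
#' `P(0) = pi + (1 - pi) e^{-mu}`, `P(y) = (1 - pi) Poisson(y; mu)` for y > 0.
#'
#' @inheritParams poisson_logpmf
#' @param pi Structural-zero probability in `[0, 1]`.
#' @return `log P(Y = y)`.
#' @export
zip_logpmf <- function(y, mu, pi) {
  .check_count(y)
  if (any(mu <= 0)) stop("mu must be positive")
  if (any(pi < 0 | pi > 1)) stop("pi must lie in [0, 1]")
  r <- log1p(-pi) + stats::dpois(y, mu, log = TRUE)
  at0 <- y == 0
  if (any(at0)) {
    p0 <- recycle_at(pi, at0)
    m0 <- recycle_at(mu, at0)
    r[at0] <- log(p0 + (1 - p0) * exp(-m0))
  }
  r
}

#' Zero-inflated negative binomial log probability mass
#'
#' `P(0) = pi + (1 - pi) (theta/(theta + mu))^theta`,
#' `P(y) = (1 - pi) NB(y; mu, theta)` for y > 0.
#'
#' @inheritParams negbin_logpmf
#' @param pi Structural-zero probability in `[0, 1]`.
#' @return `log P(Y = y)`.
#' @export
zinb_logpmf <- function(y, mu, theta, pi) {
  .check_count(y)
  if (any(mu <= 0)) stop("mu must be positive")
  if (any(theta <= 0)) stop("theta must be positive")
  if (any(pi < 0 | pi > 1)) stop("pi must lie in [0, 1]")
  r <- log1p(-pi) + stats::dnbinom(y, size = theta, mu = mu, log = TRUE)
  at0 <- y == 0
  if (any(at0)) {
    p0 <- recycle_at(pi, at0)
    m0 <- recycle_at(mu, at0)
    t0 <- recycle_at(theta, at0)
    r[at0] <- log(p0 + (1 - p0) * exp(t0 * (log(t0) - log(t0 + m0))))
  }
  r
}

recycle_at <- function(x, idx) if (length(x) == 1L) x else x[idx]

#' Observed-data ZINB log-likelihood
#'
#' Sums [zinb_logpmf()] over observations with `mu_i = exp(X_count beta)` and
#' `pi_i = plogis(X_zero gamma)`.
#'
#' @param data A [zic_data()] object.
#' @param beta Count-component coefficients (with intercept).
#' @param gamma Zero-component coefficients (with intercept).
#' @param theta Positive dispersion.
#' @return Scalar log-likelihood.
#' @export
zinb_loglik <- function(data, beta, gamma, theta = 1) {
  stopifnot(inherits(data, "zic_data"))
  mu <- .clip_exp(drop(data$X_count %*% beta))
  pi <- stats::plogis(drop(data$X_zero %*% gamma))
  ll <- sum(zinb_logpmf(data$y, mu, theta, pi))
  if (!is.finite(ll)) stop("non-finite ZINB log-likelihood")
  ll
}

#' Observed-data ZIP log-likelihood
#'
#' @inheritParams zinb_loglik
#' @return Scalar log-likelihood.
#' @export
zip_loglik <- function(data, beta, gamma) {
  stopifnot(inherits(data, "zic_data"))
  mu <- .clip_exp(drop(data$X_count %*% beta))
  pi <- stats::plogis(drop(data$X_zero %*% gamma))
  ll <- sum(zip_logpmf(data$y, mu, pi))
  if (!is.finite(ll)) stop("non-finite ZIP log-likelihood")
  ll
}

#' Posterior probability of the structural-zero state
#'
#' The E-step quantity of the mixture EM: for `y > 0` the posterior is 0;
#' for `y = 0` it is `pi / (pi + (1 - pi) P_count(0))` where `P_count(0)` is
#' the count-component mass at zero (`e^{-mu}` for ZIP,
#' `(theta/(theta+mu))^theta` for ZINB; `theta = Inf` selects the Poisson
#' count component).
#'
#' @param y Nonnegative integer count(s).
#' @param mu Positive count-component mean(s).
#' @param theta Positive dispersion, or `Inf` for a Poisson count component.
#' @param pi Structural-zero probability in `[0, 1]`.
#' @return Posterior membership probabilities in `[0, 1]`.
#' @export
posterior_zero_prob <- function(y, mu, theta, pi) {
  .check_count(y)
  if (any(mu <= 0)) stop("mu must be positive")
  if (any(pi < 0 | pi > 1)) stop("pi must lie in [0, 1]")
  p0 <- if (all(is.infinite(theta))) exp(-mu)
        else exp(theta * (log(theta) - log(theta + mu)))
  z <- pi / (pi + (1 - pi) * p0)
  z[y > 0] <- 0
  z
}
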