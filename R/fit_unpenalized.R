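#' Weighted IWLS fit of a one-component GLM
#'
#' Thin wrapper around [stats::glm.fit()] covering the three component
#' likelihoods used throughout the package: Poisson and fixed-dispersion
#' negative binomial for the count part (log link) and binomial/logistic for
#' the zero part (logit link, fractional responses allowed). Per-observation
#' prior weights are supported, as required by the EM M-steps.
#'
#' @param X Design matrix including an intercept column.
#' @param y Response vector; for `family = "binomial"` values in `[0, 1]`.
#' @param family One of `"poisson"`, `"negbin"`, `"binomial"`.
#' @param theta Dispersion for `family = "negbin"`.
#' @param prior_weights Nonnegative per-observation weights.
#' @param start Optional starting coefficients.
#' @param maxit,tol IWLS iteration cap and convergence tolerance.
#' @return List with `coefficients`, `fitted`, `loglik` (prior-weighted),
#'   `se`, `converged`, `n_iter`.
#' @export
irls_glm_fit <- function(X, y, family = c("poisson", "negbin", "binomial"),
                         theta = 1, prior_weights = NULL, start = NULL,
                         maxit = 100, tol = 1e-8) {
  family <- match.arg(family)
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(prior_weights)) prior_weights <- rep(1, n)
  if (any(prior_weights < 0)) stop("prior weights must be nonnegative")
  fam <- switch(family,
    poisson = stats::poisson(),
    negbin = MASS::negative.binomial(theta),
    # quasibinomial: identical IWLS to binomial, tolerates fractional y
    binomial = stats::quasibinomial())
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(
      X, y, weights = prior_weights, family = fam, start = start,
      control = stats::glm.control(epsilon = tol, maxit = maxit))),
    error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients) || any(!is.finite(fit$coefficients))) {
    return(list(coefficients = rep(NA_real_, ncol(X)), fitted = rep(NA_real_, n),
                loglik = NA_real_, se = rep(NA_real_, ncol(X)),
                converged = FALSE, n_iter = if (is.null(fit)) 0L else fit$iter))
  }
  mu <- fit$fitted.values
  ll <- switch(family,
    poisson = sum(prior_weights * stats::dpois(y, mu, log = TRUE)),
    negbin = sum(prior_weights * stats::dnbinom(y, size = theta, mu = mu, log = TRUE)),
    binomial = sum(prior_weights * (y * log(pmax(mu, 1e-300)) +
                                    (1 - y) * log(pmax(1 - mu, 1e-300)))))
  se <- .glm_wald_se(X, fit$weights)
  list(coefficients = fit$coefficients, fitted = mu, loglik = ll, se = se,
       converged = fit$converged, n_iter = fit$iter)
}

## Wald SEs from the converged IWLS weights (expected information, dispersion 1)
.glm_wald_se <- function(X, w) {
  XtWX <- crossprod(X * sqrt(pmax(w, 0)))
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(rep(NA_real_, ncol(X)))
  sqrt(diag(chol2inv(ch)))
}

#' Maximum-likelihood fit of a count or zero-inflated count model
#'
#' Fits one of the four regression families to a [zic_data()] object.
#' Poisson and negative binomial (fixed `theta`) fits use IWLS; the
#' zero-inflated models are fit by an EM algorithm alternating the posterior
#' structural-zero probabilities ([posterior_zero_prob()]) with two weighted
#' IWLS solves (count component with weights `1 - z`, logistic component on
#' the fractional posteriors). The observed-data log-likelihood is monotone
#' non-decreasing across EM iterations.
#'
#' Wald standard errors for the mixture models come from the analytic
#' observed information (negative Hessian) of the observed-data
#' log-likelihood at the optimum. Non-convergence, a non-finite
#' log-likelihood, or a singular/non-positive-definite information matrix are
#' all reported as `converged = FALSE` (non-identifiability).
#'
#' @param data A [zic_data()] object.
#' @param family `"poisson"`, `"negbin"`, `"zip"`, or `"zinb"`.
#' @param theta Fixed dispersion for the NB-based families (default 1).
#' @param estimate_theta If `TRUE` (ZINB only), `theta` is updated each EM
#'   cycle by one-dimensional maximization of the observed log-likelihood.
#' @param se Compute Wald standard errors (skip for speed in pure
#'   estimation-error studies).
#' @param control List with `tol` (relative log-likelihood change, default
#'   1e-8) and `maxit` (EM iteration cap, default 500).
#' @return A `count_fit` object: `family`, `beta`, `gamma` (mixture families
#'   only), `theta`, `loglik`, `se_beta`, `se_gamma`, `converged`, `n_iter`,
#'   `loglik_trace`.
#' @export
fit_unpenalized <- function(data, family = c("poisson", "negbin", "zip", "zinb"),
                            theta = 1, estimate_theta = FALSE, se = TRUE,
                            control = list()) {
  family <- match.arg(family)
  stopifnot(inherits(data, "zic_data"))
  ctl <- utils::modifyList(list(tol = 1e-8, maxit = 500), control)
  n <- length(data$y)
  if (n <= ncol(data$X_count))
    warning("fewer observations than count-model parameters; fit may be unidentifiable")
  if (family %in% c("poisson", "negbin")) {
    f <- irls_glm_fit(data$X_count, data$y, if (family == "poisson") "poisson" else "negbin",
                      theta = theta, maxit = 500)
    out <- list(family = family, beta = f$coefficients, gamma = NULL,
                theta = if (family == "poisson") Inf else theta,
                loglik = f$loglik, se_beta = if (se) f$se else NULL, se_gamma = NULL,
                converged = f$converged && all(is.finite(f$coefficients)) && is.finite(f$loglik),
                n_iter = f$n_iter, loglik_trace = f$loglik)
    if (se && out$converged && any(!is.finite(f$se))) out$converged <- FALSE
    return(structure(out, class = "count_fit"))
  }
  .fit_zi_em(data, family, theta, estimate_theta, se, ctl)
}

.fit_zi_em <- function(data, family, theta, estimate_theta, se, ctl) {
  y <- data$y; X <- data$X_count; Z <- data$X_zero
  count_fam <- if (family == "zip") "poisson" else "negbin"
  th <- if (family == "zip") Inf else theta
  obs_ll <- function(beta, gamma, th) {
    mu <- .clip_exp(drop(X %*% beta))
    pi <- stats::plogis(drop(Z %*% gamma))
    if (family == "zip") sum(zip_logpmf(y, mu, pi)) else sum(zinb_logpmf(y, mu, th, pi))
  }
  fail <- function(n_iter, trace) structure(list(
    family = family, beta = rep(NA_real_, ncol(X)), gamma = rep(NA_real_, ncol(Z)),
    theta = th, loglik = NA_real_, se_beta = NULL, se_gamma = NULL,
    converged = FALSE, n_iter = n_iter, loglik_trace = trace), class = "count_fit")

  if (!any(y == 0)) {
    # degenerate: no zeros, the mixture collapses onto the count component
    f <- irls_glm_fit(X, y, count_fam, theta = theta)
    gamma <- c(-20, rep(0, ncol(Z) - 1L))
    out <- structure(list(family = family, beta = f$coefficients, gamma = gamma,
                          theta = th, loglik = obs_ll(f$coefficients, gamma, th),
                          se_beta = if (se) f$se else NULL, se_gamma = NULL,
                          converged = f$converged, n_iter = f$n_iter,
                          loglik_trace = NULL, note = "no zero counts: mixture collapsed"),
                     class = "count_fit")
    return(out)
  }

  f0 <- irls_glm_fit(X, y, count_fam, theta = theta)
  if (!f0$converged) f0$coefficients <- c(log(mean(y) + 0.1), rep(0, ncol(X) - 1L))
  beta <- f0$coefficients
  p0hat <- min(max(mean(y == 0), 0.02), 0.98)
  gamma <- c(stats::qlogis(p0hat / 2 + 0.01), rep(0, ncol(Z) - 1L))
  ll <- tryCatch(obs_ll(beta, gamma, th), error = function(e) NA_real_)
  if (!is.finite(ll)) return(fail(0L, NULL))
  trace <- ll
  converged <- FALSE
  it <- 0L
  while (it < ctl$maxit) {
    it <- it + 1L
    mu <- .clip_exp(drop(X %*% beta))
    pi <- stats::plogis(drop(Z %*% gamma))
    z <- posterior_zero_prob(y, mu, th, pi)
    mc <- irls_glm_fit(X, y, count_fam, theta = if (family == "zip") 1 else th,
                       prior_weights = 1 - z, start = beta)
    mz <- irls_glm_fit(Z, z, "binomial", start = gamma)
    if (anyNA(mc$coefficients) || anyNA(mz$coefficients)) return(fail(it, trace))
    beta <- mc$coefficients; gamma <- mz$coefficients
    if (estimate_theta && family == "zinb") {
      op <- stats::optimize(function(lt) obs_ll(beta, gamma, exp(lt)),
                            interval = c(-5, 5), maximum = TRUE, tol = 1e-4)
      th <- exp(op$maximum)
    }
    ll_new <- tryCatch(obs_ll(beta, gamma, th), error = function(e) NA_real_)
    if (!is.finite(ll_new)) return(fail(it, trace))
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll) < ctl$tol * (abs(ll) + 1)) { converged <- TRUE; ll <- ll_new; break }
    ll <- ll_new
  }
  # estimates saturating the linear-predictor clip bound mean the likelihood
  # is evaluated on a degenerate plateau: count as non-identifiable
  if (max(abs(drop(X %*% beta))) >= .CLIP - 1e-6 ||
      max(abs(drop(Z %*% gamma))) >= .CLIP - 1e-6) converged <- FALSE
  out <- list(family = family, beta = beta, gamma = gamma, theta = th,
              loglik = ll, se_beta = NULL, se_gamma = NULL,
              converged = converged, n_iter = it, loglik_trace = trace)
  if (se) {
    info <- zi_observed_info(X, Z, y, beta, gamma, th)
    V <- tryCatch(chol2inv(chol(info)), error = function(e) NULL)
    if (is.null(V) || any(diag(V) <= 0)) {
      out$converged <- FALSE
    } else {
      s <- sqrt(diag(V))
      out$se_beta <- s[seq_len(ncol(X))]
      out$se_gamma <- s[ncol(X) + seq_len(ncol(Z))]
    }
  }
  structure(out, class = "count_fit")
}

#' Observed information of a zero-inflated count model
#'
#' Analytic negative Hessian of the observed-data log-likelihood of a ZIP
#' (`theta = Inf`) or ZINB model with respect to `(beta, gamma)` at the
#' supplied parameter values.
#'
#' @param X,Z Count- and zero-component designs (with intercepts).
#' @param y Count response.
#' @param beta,gamma Coefficients.
#' @param theta Dispersion; `Inf` for the ZIP model.
#' @return The `(p+q) x (p+q)` observed information matrix.
#' @export
zi_observed_info <- function(X, Z, y, beta, gamma, theta = 1) {
  eta <- pmin(pmax(drop(X %*% beta), -.CLIP), .CLIP)
  mu <- exp(eta)
  pi <- stats::plogis(drop(Z %*% gamma))
  zip <- is.infinite(theta)
  l_ee <- l_xx <- l_ex <- numeric(length(y))
  pos <- y > 0
  if (any(pos)) {
    m <- mu[pos]
    l_ee[pos] <- if (zip) -m else -(y[pos] + theta) * theta * m / (m + theta)^2
    l_xx[pos] <- -pi[pos] * (1 - pi[pos])
  }
  if (any(!pos)) {
    m <- mu[!pos]; p <- pi[!pos]
    if (zip) {
      q <- exp(-m); qp <- -q * m; qpp <- q * m * (m - 1)
    } else {
      q <- exp(theta * (log(theta) - log(theta + m)))
      qp <- -q * theta * m / (theta + m)
      qpp <- q * theta^2 * m * (m - 1) / (theta + m)^2
    }
    A <- p + (1 - p) * q
    le <- (1 - p) * qp / A
    l_ee[!pos] <- (1 - p) * qpp / A - le^2
    lx <- p * (1 - p) * (1 - q) / A
    l_xx[!pos] <- p * (1 - p) * (1 - 2 * p) * (1 - q) / A - lx^2
    l_ex[!pos] <- -p * (1 - p) * qp * (A + (1 - q) * (1 - p)) / A^2
  }
  Hbb <- crossprod(X, X * l_ee)
  Hgg <- crossprod(Z, Z * l_xx)
  Hbg <- crossprod(X, Z * l_ex)
  -rbind(cbind(Hbb, Hbg), cbind(t(Hbg), Hgg))
}

#' @export
print.count_fit <- function(x, ...) {
  cat(sprintf("%s fit: loglik = %s, converged = %s (%d iterations)\n",
              toupper(x$family),
              if (is.finite(x$loglik)) sprintf("%.3f", x$loglik) else "NA",
              x$converged, x$n_iter))
  cat("count coefficients:\n"); print(x$beta)
  if (!is.null(x$gamma)) { cat("zero coefficients:\n"); print(x$gamma) }
  invisible(x)
}

#' @export
coef.count_fit <- function(object, ...) {
  list(count = object$beta, zero = object$gamma)
}

#' Wald z-tests for the coefficients of a fitted count model
#'
#' @param fit A converged `count_fit` with standard errors.
#' @return Data frame with component, term, estimate, se, z and p-value.
#' @export
wald_tests <- function(fit) {
  stopifnot(inherits(fit, "count_fit"))
  if (is.null(fit$se_beta)) stop("fit has no standard errors (was se = FALSE?)")
  tab <- data.frame(component = "count",
                    term = names(fit$beta) %||% paste0("b", seq_along(fit$beta) - 1L),
                    estimate = unname(fit$beta), se = unname(fit$se_beta))
  if (!is.null(fit$gamma) && !is.null(fit$se_gamma)) {
    tab <- rbind(tab, data.frame(
      component = "zero",
      term = names(fit$gamma) %||% paste0("g", seq_along(fit$gamma) - 1L),
      estimate = unname(fit$gamma), se = unname(fit$se_gamma)))
  }
  tab$z <- tab$estimate / tab$se
  tab$p <- 2 * stats::pnorm(-abs(tab$z))
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a
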