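#' Soft-thresholding operator
#'
#' `sign(z) * max(|z| - lam, 0)`, the coordinate-descent update kernel.
#'
#' @param z Numeric vector.
#' @param lam Nonnegative threshold.
#' @return Thresholded values.
#' @export
soft_threshold <- function(z, lam) {
  if (any(lam < 0)) stop("lam must be nonnegative")
  sign(z) * pmax(abs(z) - lam, 0)
}

#' BIC from a deviance and a parameter count
#'
#' @param neg2loglik `-2 log L` at the estimate.
#' @param d Number of non-zero parameters.
#' @param n Sample size.
#' @return `neg2loglik + d * log(n)`.
#' @export
bic_value <- function(neg2loglik, d, n) neg2loglik + d * log(n)

#' Per-coefficient penalty weights for the two model components
#'
#' @param w1 Nonnegative weights for the non-intercept count coefficients
#'   (length p); `Inf` excludes a variable.
#' @param w2 Nonnegative weights for the non-intercept zero coefficients
#'   (length q).
#' @return A `penalty_spec` object. Intercepts always carry weight 0.
#' @export
penalty_spec <- function(w1, w2 = numeric(0)) {
  if (any(w1 < 0, na.rm = TRUE) || any(w2 < 0, na.rm = TRUE))
    stop("penalty weights must be nonnegative")
  if (anyNA(w1) || anyNA(w2)) stop("penalty weights must not be NA")
  structure(list(w1 = as.numeric(w1), w2 = as.numeric(w2)), class = "penalty_spec")
}

#' Unit penalty weights (plain LASSO)
#'
#' @param data A [zic_data()] object.
#' @return A `penalty_spec` with every weight 1, under which the adaptive
#'   solver reduces to the LASSO estimator.
#' @export
unit_weights <- function(data) {
  penalty_spec(rep(1, ncol(data$X_count) - 1L), rep(1, ncol(data$X_zero) - 1L))
}

#' Data-adaptive penalty weights from a pilot ZINB fit
#'
#' Weights are the reciprocal absolute pilot coefficients,
#' `w = 1 / |coef|`, computed from the unpenalized ZINB maximum-likelihood
#' fit; a pilot coefficient of exactly zero maps to an infinite weight
#' (hard exclusion). When the MLE is unavailable (non-convergence or
#' collinearity) the ridge-penalized ZINB estimate is used instead.
#'
#' @param data A [zic_data()] object.
#' @param theta Fixed dispersion of the pilot fit.
#' @param estimate_theta Estimate `theta` in the pilot fit.
#' @param fallback `"ridge"` (default) to fall back on ridge-penalized
#'   estimates, `"none"` to error when the MLE fails.
#' @return A `penalty_spec`; attribute `"pilot"` records which pilot was used.
#' @export
adaptive_weights <- function(data, theta = 1, estimate_theta = FALSE,
                             fallback = c("ridge", "none")) {
  fallback <- match.arg(fallback)
  fit <- tryCatch(
    fit_unpenalized(data, "zinb", theta = theta, estimate_theta = estimate_theta,
                    se = FALSE),
    error = function(e) NULL)
  pilot <- "mle"
  if (is.null(fit) || !fit$converged || anyNA(fit$beta) || anyNA(fit$gamma)) {
    if (fallback == "none") stop("pilot MLE unavailable and fallback disabled")
    rf <- em_ridge_zinb(data, theta = theta)
    if (is.null(rf)) stop("neither MLE nor ridge pilot estimates are available")
    b <- rf$beta; g <- rf$gamma
    pilot <- "ridge"
  } else {
    b <- fit$beta; g <- fit$gamma
  }
  ws <- penalty_spec(1 / abs(b[-1]), if (length(g) > 1L) 1 / abs(g[-1]) else numeric(0))
  attr(ws, "pilot") <- pilot
  attr(ws, "pilot_beta") <- b
  attr(ws, "pilot_gamma") <- g
  ws
}

## --- internal standardization helpers -------------------------------------

## Center and scale non-intercept columns; constant columns get scale 1 and
## become identically zero (their coefficients stay 0).
.std_design <- function(X) {
  p <- ncol(X)
  center <- c(0, if (p > 1L) colMeans(X[, -1L, drop = FALSE]) else numeric(0))
  scale <- rep(1, p)
  if (p > 1L) {
    s <- apply(X[, -1L, drop = FALSE], 2L, stats::sd)
    s[!is.finite(s) | s < 1e-12] <- 1
    scale[-1L] <- s
  }
  Xs <- X
  if (p > 1L) Xs[, -1L] <- sweep(sweep(X[, -1L, drop = FALSE], 2L, center[-1L]),
                                 2L, scale[-1L], "/")
  list(X = Xs, center = center, scale = scale)
}

.to_std <- function(b, ctx) {
  bs <- b * ctx$scale
  bs[1L] <- b[1L] + sum(b[-1L] * ctx$center[-1L])
  bs
}

.from_std <- function(bs, ctx) {
  b <- bs / ctx$scale
  b[1L] <- bs[1L] - sum(bs[-1L] * ctx$center[-1L] / ctx$scale[-1L])
  names(b) <- colnames(ctx$X)
  b
}

## weights on the standardized scale: penalizing w_j |beta_orig_j| equals
## penalizing (w_j / s_j) |beta_std_j|
.std_pw <- function(w, ctx) c(0, w / ctx$scale[-1L])

## --- single-component coordinate-descent solvers ---------------------------

#' Coordinate-descent solve of a weighted penalized NB regression
#'
#' Minimizes `-2 * sum(obs_weights * logNB(y; exp(X b), theta)) +
#' lambda * sum(w |b_j|)` over the non-intercept coefficients by cyclic
#' coordinate descent with soft-thresholding on the IWLS quadratic
#' approximation. The intercept is never penalized. Predictors are
#' standardized internally and coefficients returned on the original scale.
#'
#' @param X Design matrix including an intercept column.
#' @param y Count response.
#' @param obs_weights Per-observation weights in `[0, 1]` (the EM supplies
#'   `1 - z`).
#' @param lambda Nonnegative penalty level.
#' @param pen_weights Per-coefficient weights, length `ncol(X) - 1`;
#'   `Inf` excludes a variable.
#' @param theta NB dispersion (`Inf` for a Poisson count component).
#' @param start Optional starting coefficients (original scale).
#' @return List with `coefficients`, `objective`, `converged`, `n_iter`.
#' @export
cd_penalized_negbin <- function(X, y, obs_weights = NULL, lambda = 0,
                                pen_weights = NULL, theta = 1, start = NULL) {
  .cd_component(X, y, obs_weights, lambda, pen_weights, family = 0L,
                theta = theta, start = start)
}

#' Coordinate-descent solve of a penalized logistic regression
#'
#' Minimizes `-2 * sum(z log p + (1-z) log(1-p)) + lambda * sum(w |g_j|)`
#' for fractional responses `z` in `[0, 1]` (the EM posterior memberships).
#'
#' @param X Zero-component design matrix including an intercept column.
#' @param zhat Fractional responses in `[0, 1]`.
#' @param lambda Nonnegative penalty level.
#' @param pen_weights Per-coefficient weights, length `ncol(X) - 1`.
#' @param start Optional starting coefficients (original scale).
#' @return List with `coefficients`, `objective`, `converged`, `n_iter`.
#' @export
cd_penalized_logistic <- function(X, zhat, lambda = 0, pen_weights = NULL,
                                  start = NULL) {
  if (any(zhat < 0 | zhat > 1)) stop("zhat must lie in [0, 1]")
  .cd_component(X, zhat, NULL, lambda, pen_weights, family = 1L,
                theta = 1, start = start)
}

.cd_component <- function(X, y, obs_weights, lambda, pen_weights, family,
                          theta, start) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (is.null(obs_weights)) obs_weights <- rep(1, n)
  if (any(obs_weights < 0)) stop("obs_weights must be nonnegative")
  if (lambda < 0) stop("lambda must be nonnegative")
  if (is.null(pen_weights)) pen_weights <- rep(1, p - 1L)
  if (length(pen_weights) != p - 1L) stop("pen_weights must have ncol(X) - 1 entries")
  ctx <- .std_design(X)
  st <- if (is.null(start)) {
    if (family == 0L) c(log(sum(obs_weights * y) / max(sum(obs_weights), 1e-8) + 0.05),
                        rep(0, p - 1L))
    else c(stats::qlogis(min(max(mean(y), 0.02), 0.98)), rep(0, p - 1L))
  } else .to_std(start, ctx)
  fit <- .cd_pglm_cpp(ctx$X, y, obs_weights, family, theta, lambda,
                      .std_pw(pen_weights, ctx), st)
  list(coefficients = .from_std(fit$beta, ctx), objective = fit$objective,
       converged = fit$converged, n_iter = fit$n_iter)
}

## --- penalized EM ----------------------------------------------------------

## Core penalized EM on pre-standardized designs (warm-start friendly).
## beta/gamma in and out are on the standardized scale.
.em_pen_std <- function(y, cx, cz, lambda1, lambda2, w1s, w2s, beta, gamma,
                        theta = 1, estimate_theta = FALSE, tol = 1e-6,
                        maxit = 300L, m_iter = 3L) {
  n <- length(y)
  pen <- function(b, g) {
    f1 <- is.finite(w1s) & w1s > 0
    f2 <- is.finite(w2s) & w2s > 0
    s1 <- sum(w1s[f1] * abs(b[f1]))
    s2 <- sum(w2s[f2] * abs(g[f2]))
    (if (s1 > 0) lambda1 * s1 else 0) + (if (s2 > 0) lambda2 * s2 else 0)
  }
  obs_ll <- function(b, g, th) {
    mu <- .clip_exp(drop(cx %*% b))
    pi <- stats::plogis(drop(cz %*% g))
    sum(zinb_logpmf(y, mu, th, pi))
  }
  th <- theta
  Q <- -2 * obs_ll(beta, gamma, th) + pen(beta, gamma)
  trace <- Q
  converged <- FALSE
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    mu <- .clip_exp(drop(cx %*% beta))
    pi <- stats::plogis(drop(cz %*% gamma))
    z <- posterior_zero_prob(y, mu, th, pi)
    # partial M-steps (a few IWLS rounds) keep the generalized EM monotone
    # while sharing the convergence control with the outer loop
    mb <- .cd_pglm_cpp(cx, y, 1 - z, 0L, th, lambda1, w1s, beta,
                       maxit_irls = m_iter)
    beta <- mb$beta
    mg <- .cd_pglm_cpp(cz, z, rep(1, n), 1L, 1, lambda2, w2s, gamma,
                       maxit_irls = m_iter)
    gamma <- mg$beta
    if (estimate_theta) {
      op <- stats::optimize(function(lt) obs_ll(beta, gamma, exp(lt)),
                            interval = c(-5, 5), maximum = TRUE, tol = 1e-4)
      th <- exp(op$maximum)
    }
    Q_new <- -2 * obs_ll(beta, gamma, th) + pen(beta, gamma)
    trace <- c(trace, Q_new)
    done <- abs(Q_new - Q) < tol * (abs(Q) + 1)
    Q <- Q_new
    if (done) { converged <- TRUE; break }
  }
  list(beta = beta, gamma = gamma, theta = th, objective = Q,
       loglik = obs_ll(beta, gamma, th), converged = converged,
       n_iter = it, objective_trace = trace)
}

#' EM adaptive LASSO fit of a penalized ZINB model at fixed penalties
#'
#' Minimizes `-2 log L(beta, gamma) + lambda1 sum(w1 |beta_j|) +
#' lambda2 sum(w2 |gamma_j|)` (observed-data ZINB likelihood, intercepts
#' unpenalized) by an EM algorithm: the E-step computes posterior
#' structural-zero memberships, the M-step runs coordinate descent on a
#' weighted penalized NB objective and a penalized logistic objective.
#' Returned coefficients are sparse with exact zeros.
#'
#' @param data A [zic_data()] object.
#' @param lambda1,lambda2 Nonnegative shrinkage levels for the count and
#'   zero components.
#' @param weights A [penalty_spec()]; default unit weights (plain LASSO).
#' @param theta Fixed dispersion (default 1).
#' @param estimate_theta Update `theta` each EM cycle by one-dimensional
#'   likelihood maximization.
#' @param start Optional list with `beta`, `gamma` starting values
#'   (original scale).
#' @param control List with `tol` (relative change of the penalized
#'   objective, default 1e-6; the BIC-selected point is re-solved at 1e-10)
#'   and `maxit` (default 300).
#' @return A `penalized_fit`: sparse `beta`, `gamma`, `theta`, `lambda1`,
#'   `lambda2`, `loglik` (observed data), `objective`, `df`, `bic`,
#'   `support_count`, `support_zero`, `converged`, `n_iter`,
#'   `objective_trace`.
#' @export
em_penalized_zinb <- function(data, lambda1 = 0, lambda2 = 0, weights = NULL,
                              theta = 1, estimate_theta = FALSE, start = NULL,
                              control = list()) {
  stopifnot(inherits(data, "zic_data"))
  ctl <- utils::modifyList(list(tol = 1e-6, maxit = 300L), control)
  if (is.null(weights)) weights <- unit_weights(data)
  cxs <- .std_design(data$X_count)
  czs <- .std_design(data$X_zero)
  w1s <- .std_pw(weights$w1, cxs)
  w2s <- if (ncol(data$X_zero) > 1L) .std_pw(weights$w2, czs) else 0
  y <- data$y
  if (is.null(start)) {
    b0 <- c(log(mean(y) + 0.05), rep(0, ncol(data$X_count) - 1L))
    g0 <- c(stats::qlogis(min(max(mean(y == 0) / 2 + 0.01, 0.02), 0.98)),
            rep(0, ncol(data$X_zero) - 1L))
  } else {
    b0 <- .to_std(start$beta, cxs)
    g0 <- .to_std(start$gamma, czs)
  }
  em <- .em_pen_std(y, cxs$X, czs$X, lambda1, lambda2, w1s, w2s, b0, g0,
                    theta = theta, estimate_theta = estimate_theta,
                    tol = ctl$tol, maxit = ctl$maxit)
  .as_penalized_fit(em, cxs, czs, lambda1, lambda2, length(y), estimate_theta,
                    weights)
}

.as_penalized_fit <- function(em, cxs, czs, lambda1, lambda2, n,
                              estimate_theta, weights) {
  beta <- .from_std(em$beta, cxs)
  gamma <- .from_std(em$gamma, czs)
  df <- sum(beta != 0) + sum(gamma != 0) + as.integer(estimate_theta)
  structure(list(
    beta = beta, gamma = gamma, theta = em$theta,
    lambda1 = lambda1, lambda2 = lambda2,
    loglik = em$loglik, objective = em$objective,
    df = df, bic = bic_value(-2 * em$loglik, df, n),
    support_count = which(beta[-1] != 0), support_zero = which(gamma[-1] != 0),
    converged = em$converged, n_iter = em$n_iter,
    objective_trace = em$objective_trace, weights = weights),
    class = "penalized_fit")
}

#' @export
print.penalized_fit <- function(x, ...) {
  cat(sprintf(
    "penalized ZINB fit: lambda1 = %.4g, lambda2 = %.4g, df = %d, BIC = %.2f\n",
    x$lambda1, x$lambda2, x$df, x$bic))
  cat(sprintf("count support: %s\n",
              if (length(x$support_count)) paste(x$support_count, collapse = ", ")
              else "(empty)"))
  invisible(x)
}

#' Regularization path with BIC tuning-parameter selection
#'
#' Builds a grid of `(lambda1, lambda2)` pairs -- log-spaced from the
#' data-driven maximum (smallest penalty with an all-zero penalized
#' solution at the null model) down to a fraction of it -- fits
#' [em_penalized_zinb()] at every point with warm starts along decreasing
#' `lambda1`, and selects the fit minimizing
#' `BIC = -2 log L + d log(n)` with `d` the number of non-zero parameters.
#' Ties break toward the larger (sparser) penalty. When the zero-component
#' design is intercept-only the `lambda2` dimension collapses to 0.
#'
#' @inheritParams em_penalized_zinb
#' @param weights A [penalty_spec()]; unit weights give the LASSO path,
#'   [adaptive_weights()] the adaptive LASSO path.
#' @param nlambda1,nlambda2 Grid sizes (defaults 30 and 10).
#' @param lambda_min_ratio Smallest penalty as a fraction of the maximum
#'   (default 0.001).
#' @param lambda1,lambda2 Optional explicit grids overriding the automatic
#'   construction.
#' @return A `reg_path`: `path` (data frame with lambda1, lambda2, df,
#'   loglik, bic, converged per grid point), `coefficients` (per-point
#'   sparse beta/gamma), `selected` (index of the BIC minimizer), and
#'   `fit` (the selected `penalized_fit`).
#' @export
build_path_select_bic <- function(data, weights = NULL, nlambda1 = 30L,
                                  nlambda2 = 10L, lambda_min_ratio = 0.001,
                                  lambda1 = NULL, lambda2 = NULL, theta = 1,
                                  estimate_theta = FALSE, control = list()) {
  stopifnot(inherits(data, "zic_data"))
  ctl <- utils::modifyList(list(tol = 1e-6, maxit = 300L), control)
  if (is.null(weights)) weights <- unit_weights(data)
  y <- data$y; n <- length(y)
  cxs <- .std_design(data$X_count)
  czs <- .std_design(data$X_zero)
  w1s <- .std_pw(weights$w1, cxs)
  w2s <- if (ncol(data$X_zero) > 1L) .std_pw(weights$w2, czs) else 0

  # null model: intercepts only, used for the data-driven lambda_max
  null_fit <- .em_pen_std(y, cxs$X, czs$X, Inf, Inf,
                          rep(Inf, ncol(cxs$X)), rep(Inf, ncol(czs$X)),
                          c(log(mean(y) + 0.05), rep(0, ncol(cxs$X) - 1L)),
                          c(stats::qlogis(min(max(mean(y == 0) / 2 + 0.01, 0.02), 0.98)),
                            rep(0, ncol(czs$X) - 1L)),
                          theta = theta, tol = 1e-10, maxit = 200L)
  th0 <- null_fit$theta
  mu0 <- .clip_exp(drop(cxs$X %*% null_fit$beta))
  pi0 <- stats::plogis(drop(czs$X %*% null_fit$gamma))
  z0 <- posterior_zero_prob(y, mu0, th0, pi0)
  score1 <- -2 * drop(crossprod(cxs$X, (1 - z0) * (y - (y + th0) * mu0 / (mu0 + th0))))
  score2 <- -2 * drop(crossprod(czs$X, z0 - pi0))
  gridify <- function(score, ws, nl, explicit) {
    if (!is.null(explicit)) return(sort(unique(as.numeric(explicit)), decreasing = TRUE))
    fin <- is.finite(ws) & ws > 0
    fin[1L] <- FALSE
    if (!any(fin)) return(0)
    lmax <- max(abs(score[fin]) / ws[fin]) * 1.001
    if (!is.finite(lmax) || lmax <= 0) return(0)
    exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nl))
  }
  l1_grid <- gridify(score1, w1s, nlambda1, lambda1)
  l2_grid <- if (ncol(data$X_zero) > 1L) gridify(score2, w2s, nlambda2, lambda2) else 0

  pts <- expand.grid(lambda1 = l1_grid, lambda2 = l2_grid,
                     KEEP.OUT.ATTRS = FALSE)
  # order: lambda2 descending outer, lambda1 descending inner (warm starts)
  pts <- pts[order(-pts$lambda2, -pts$lambda1), , drop = FALSE]
  fits <- vector("list", nrow(pts))
  warm_b <- null_fit$beta; warm_g <- null_fit$gamma
  sweep_b <- warm_b; sweep_g <- warm_g
  prev_l2 <- NA_real_
  for (i in seq_len(nrow(pts))) {
    if (!identical(pts$lambda2[i], prev_l2)) {
      # new lambda1 sweep: restart from the first solution of the previous sweep
      warm_b <- sweep_b; warm_g <- sweep_g
      prev_l2 <- pts$lambda2[i]
      new_sweep <- TRUE
    } else new_sweep <- FALSE
    em <- .em_pen_std(y, cxs$X, czs$X, pts$lambda1[i], pts$lambda2[i],
                      w1s, w2s, warm_b, warm_g, theta = theta,
                      estimate_theta = estimate_theta, tol = ctl$tol,
                      maxit = ctl$maxit)
    fits[[i]] <- em
    warm_b <- em$beta; warm_g <- em$gamma
    if (new_sweep) { sweep_b <- em$beta; sweep_g <- em$gamma }
  }
  pf <- lapply(seq_along(fits), function(i)
    .as_penalized_fit(fits[[i]], cxs, czs, pts$lambda1[i], pts$lambda2[i], n,
                      estimate_theta, weights))
  path <- data.frame(
    lambda1 = pts$lambda1, lambda2 = pts$lambda2,
    df = vapply(pf, `[[`, 0L, "df"),
    loglik = vapply(pf, `[[`, 0, "loglik"),
    bic = vapply(pf, `[[`, 0, "bic"),
    converged = vapply(pf, `[[`, TRUE, "converged"))
  ok <- which(path$converged & is.finite(path$bic))
  if (!length(ok)) stop("no converged fits on the regularization grid")
  sel <- ok[which.min(path$bic[ok])]  # first minimum = largest (sparser) penalty
  # polish the selected point to tight stationarity (cheap: one grid point)
  em_sel <- .em_pen_std(y, cxs$X, czs$X, pts$lambda1[sel], pts$lambda2[sel],
                        w1s, w2s, .to_std(pf[[sel]]$beta, cxs),
                        .to_std(pf[[sel]]$gamma, czs), theta = theta,
                        estimate_theta = estimate_theta, tol = 1e-10,
                        maxit = 200L, m_iter = 25L)
  pf[[sel]] <- .as_penalized_fit(em_sel, cxs, czs, pts$lambda1[sel],
                                 pts$lambda2[sel], n, estimate_theta, weights)
  path$df[sel] <- pf[[sel]]$df
  path$loglik[sel] <- pf[[sel]]$loglik
  path$bic[sel] <- pf[[sel]]$bic
  structure(list(path = path,
                 coefficients = lapply(pf, function(f) list(beta = f$beta, gamma = f$gamma)),
                 selected = sel, fit = pf[[sel]], weights = weights),
            class = "reg_path")
}

#' @export
print.reg_path <- function(x, ...) {
  cat(sprintf("regularization path: %d grid points, selected #%d (BIC = %.2f)\n",
              nrow(x$path), x$selected, x$path$bic[x$selected]))
  print(utils::head(x$path, 5))
  if (nrow(x$path) > 5) cat("...\n")
  invisible(x)
}

#' Write a regularization path and its selected model to disk
#'
#' Emits the path as CSV (one row per grid point) and the selected support
#' with estimates as a JSON summary.
#'
#' @param path A `reg_path` object.
#' @param file_csv,file_json Output paths.
#' @param tests Optional result of [post_selection_tests()] to include.
#' @return Invisibly, the JSON summary list.
#' @export
write_path <- function(path, file_csv, file_json, tests = NULL) {
  stopifnot(inherits(path, "reg_path"))
  utils::write.csv(path$path, file_csv, row.names = FALSE)
  fit <- path$fit
  summ <- list(lambda1 = fit$lambda1, lambda2 = fit$lambda2, df = fit$df,
               bic = fit$bic, loglik = fit$loglik,
               beta = as.list(fit$beta[fit$beta != 0]),
               gamma = as.list(fit$gamma[fit$gamma != 0]))
  if (!is.null(tests)) summ$tests <- tests
  jsonlite::write_json(summ, file_json, auto_unbox = TRUE, digits = NA)
  invisible(summ)
}

#' Karush-Kuhn-Tucker stationarity check for a penalized fit
#'
#' Verifies, on the standardized scale the solver works on, that every zero
#' coefficient satisfies `|gradient| <= lambda * w + tol` and every non-zero
#' coefficient satisfies `gradient + lambda * w * sign(coef) = 0` within
#' `tol`, where the gradient is of `-2` times the observed-data ZINB
#' log-likelihood (by Fisher's identity this equals the expected
#' complete-data gradient at the EM fixed point).
#'
#' @param fit A `penalized_fit`.
#' @param data The [zic_data()] the fit was computed on.
#' @param tol Violation tolerance on the gradient scale, relative to `n`.
#' @return List with `ok`, `max_violation_zero`, `max_violation_active`.
#' @export
kkt_check <- function(fit, data, tol = 1e-4) {
  stopifnot(inherits(fit, "penalized_fit"), inherits(data, "zic_data"))
  cxs <- .std_design(data$X_count)
  czs <- .std_design(data$X_zero)
  b <- .to_std(fit$beta, cxs)
  g <- .to_std(fit$gamma, czs)
  w1s <- .std_pw(fit$weights$w1, cxs)
  w2s <- if (ncol(data$X_zero) > 1L) .std_pw(fit$weights$w2, czs) else 0
  y <- data$y
  mu <- .clip_exp(drop(cxs$X %*% b))
  pi <- stats::plogis(drop(czs$X %*% g))
  th <- fit$theta
  z <- posterior_zero_prob(y, mu, th, pi)
  grad1 <- -2 * drop(crossprod(cxs$X, (1 - z) * (y - (y + th) * mu / (mu + th))))
  grad2 <- -2 * drop(crossprod(czs$X, z - pi))
  viol <- function(grad, coefs, lambda, ws) {
    if (!length(grad)) return(c(0, 0))
    pen <- seq_along(grad) > 1L & is.finite(ws)
    vz <- va <- 0
    for (j in which(pen)) {
      lw <- lambda * ws[j]
      if (coefs[j] == 0) vz <- max(vz, abs(grad[j]) - lw)
      else va <- max(va, abs(grad[j] + lw * sign(coefs[j])))
    }
    # intercept: plain stationarity
    va <- max(va, abs(grad[1L]))
    c(vz, va)
  }
  v1 <- viol(grad1, b, fit$lambda1, w1s)
  v2 <- viol(grad2, g, fit$lambda2, w2s)
  scale <- length(y) * tol
  list(ok = max(v1[1], v2[1]) <= scale && max(v1[2], v2[2]) <= scale,
       max_violation_zero = max(v1[1], v2[1]),
       max_violation_active = max(v1[2], v2[2]))
}

#' Post-selection Wald tests on the selected support
#'
#' Refits the unpenalized ZINB model restricted to the selected variables
#' and tests each supported coefficient with a Wald z-test at level
#' `alpha`; unselected coefficients are declared non-significant. If the
#' refit does not converge, the decisions fall back to treating every
#' selected variable as significant (with a warning).
#'
#' @param fit A `penalized_fit` (e.g. the `$fit` of
#'   [build_path_select_bic()]).
#' @param data The [zic_data()] the fit was computed on.
#' @param alpha Test level.
#' @return Data frame with one row per count-component covariate:
#'   `selected`, `estimate`, `se`, `z`, `p`, `significant`.
#' @export
post_selection_tests <- function(fit, data, alpha = 0.05) {
  stopifnot(inherits(fit, "penalized_fit"), inherits(data, "zic_data"))
  p <- ncol(data$X_count) - 1L
  out <- data.frame(variable = seq_len(p), selected = FALSE,
                    estimate = 0, se = NA_real_, z = NA_real_, p = NA_real_,
                    significant = FALSE)
  sup <- fit$support_count
  if (!length(sup)) return(out)
  out$selected[sup] <- TRUE
  supz <- fit$support_zero
  sub <- zic_data(data$y,
                  data$X_count[, 1L + sup, drop = FALSE],
                  if (length(supz)) data$X_zero[, 1L + supz, drop = FALSE] else NULL)
  refit <- tryCatch(
    fit_unpenalized(sub, "zinb", theta = fit$theta, se = TRUE),
    error = function(e) NULL)
  if (is.null(refit) || !refit$converged || is.null(refit$se_beta)) {
    warning("post-selection refit did not converge; treating selected variables as significant")
    out$estimate[sup] <- fit$beta[-1][sup]
    out$significant[sup] <- TRUE
    return(out)
  }
  est <- refit$beta[-1]; se <- refit$se_beta[-1]
  zst <- est / se
  pv <- 2 * stats::pnorm(-abs(zst))
  out$estimate[sup] <- est; out$se[sup] <- se; out$z[sup] <- zst; out$p[sup] <- pv
  out$significant[sup] <- pv < alpha
  out
}
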