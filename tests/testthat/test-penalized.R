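test_that("soft threshold and BIC arithmetic are exact", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-0.5, 1), 0)
  expect_equal(soft_threshold(c(-2, 0.3, 4), 0), c(-2, 0.3, 4))
  expect_error(soft_threshold(1, -1))
  expect_equal(bic_value(200, 5, 200), 200 + 5 * log(200))
  expect_equal(bic_value(123.4, 0, 50), 123.4)
})

test_that("adaptive weights are reciprocal pilot magnitudes with hard exclusions", {
  # algebraic contract on a synthetic pilot
  b <- c(0.3, 2, -0.5, 0)
  w <- 1 / abs(b[-1])
  expect_equal(w, c(0.5, 2, Inf))
  # deterministic on real data
  dat <- make_zinb_fixture(n = 300, seed = 23)
  w1 <- adaptive_weights(dat)
  w2 <- adaptive_weights(dat)
  expect_identical(w1$w1, w2$w1)
  expect_identical(attr(w1, "pilot"), "mle")
  mle <- fit_unpenalized(dat, "zinb", se = FALSE)
  expect_equal(w1$w1, unname(1 / abs(mle$beta[-1])))
})

test_that("zero-penalty coordinate descent agrees with unpenalized IWLS", {
  dat <- make_zinb_fixture(n = 300, seed = 29)
  g <- irls_glm_fit(dat$X_count, dat$y, "negbin", theta = 1, tol = 1e-10)
  cdf <- cd_penalized_negbin(dat$X_count, dat$y, theta = 1, lambda = 0)
  expect_lt(max(abs(cdf$coefficients - g$coefficients)) / max(abs(g$coefficients)), 1e-5)
  # logistic with fractional responses
  zh <- plogis(rnorm(300, 0, 0.4))
  gl <- irls_glm_fit(dat$X_zero, zh, "binomial")
  cdl <- cd_penalized_logistic(dat$X_zero, zh, lambda = 0)
  expect_lt(max(abs(cdl$coefficients - gl$coefficients)), 1e-6)
  # intercept-only logistic at mean 0.5 gives exactly 0
  cd0 <- cd_penalized_logistic(matrix(1, 50, 1), rep(0.5, 50))
  expect_equal(unname(cd0$coefficients), 0, tolerance = 1e-8)
})

test_that("large penalties and infinite weights force exact zeros", {
  dat <- make_zinb_fixture(n = 250, seed = 31)
  cdf <- cd_penalized_negbin(dat$X_count, dat$y, lambda = 1e7)
  expect_true(all(cdf$coefficients[-1] == 0))
  pw <- rep(1, ncol(dat$X_count) - 1L)
  pw[2] <- Inf
  for (lam in c(0.5, 5, 50)) {
    cdi <- cd_penalized_negbin(dat$X_count, dat$y, lambda = lam, pen_weights = pw)
    expect_identical(unname(cdi$coefficients[3]), 0)
  }
})

test_that("penalized logistic solve matches the glmnet objective with unit weights", {
  skip_if_not_installed("glmnet")
  set.seed(37)
  n <- 300; p <- 8
  X <- cbind(1, matrix(rnorm(n * p), n, p))
  zh <- plogis(0.4 + X[, 2] - 0.6 * X[, 4] + rnorm(n, 0, 0.3))
  obj <- function(g, lam2) {
    eta <- drop(X %*% g)
    -2 * sum(zh * eta - log1p(exp(eta))) + lam2 * sum(abs(g[-1]))
  }
  for (lam_g in c(0.05, 0.01, 0.002)) {
    gn <- glmnet::glmnet(X[, -1], cbind(1 - zh, zh), family = "binomial",
                         lambda = lam_g, standardize = FALSE, thresh = 1e-12)
    ours <- cd_penalized_logistic(X, zh, lambda = 2 * n * lam_g)
    o1 <- obj(ours$coefficients, 2 * n * lam_g)
    o2 <- obj(c(gn$a0, as.numeric(gn$beta)), 2 * n * lam_g)
    expect_lt(abs(o1 - o2) / abs(o2), 1e-6)
  }
})

test_that("the penalized EM at zero penalty reproduces the unpenalized MLE", {
  dat <- make_zinb_fixture(n = 400, seed = 41)
  mle <- fit_unpenalized(dat, "zinb", se = FALSE,
                         control = list(tol = 1e-12, maxit = 2000))
  pf <- em_penalized_zinb(dat, 0, 0, control = list(tol = 1e-12, maxit = 2000))
  expect_lt(max(abs(pf$beta - mle$beta)) / max(abs(mle$beta)), 1e-4)
  expect_lt(max(abs(pf$gamma - mle$gamma)) / max(abs(mle$gamma), 1), 1e-3)
})

test_that("the penalized EM objective is non-increasing and KKT holds at the solution", {
  for (seed in c(43, 47)) {
    dat <- make_zinb_fixture(n = 350, seed = seed)
    w <- adaptive_weights(dat)
    path <- build_path_select_bic(dat, w, nlambda1 = 12)
    tr <- path$fit$objective_trace
    expect_true(all(diff(tr) <= 1e-8 * (abs(tr[-length(tr)]) + 1)))
    kk <- kkt_check(path$fit, dat)
    expect_true(kk$ok)
    # the penalized objective at the solution does not exceed its value at
    # the unpenalized MLE plus that point's penalty
    mle <- fit_unpenalized(dat, "zinb", se = FALSE)
    pen_mle <- path$fit$lambda1 * sum(w$w1[is.finite(w$w1)] *
                                        abs(mle$beta[-1][is.finite(w$w1)]))
    expect_lte(path$fit$objective, -2 * mle$loglik + pen_mle + 1e-6)
  }
})

test_that("path construction selects by BIC with sparser tie-breaks and honest bounds", {
  dat <- make_zinb_fixture(n = 300, seed = 53)
  path <- build_path_select_bic(dat, nlambda1 = 10)
  df <- path$path
  expect_true(all(df$df >= 2 & df$df <= ncol(dat$X_count) + ncol(dat$X_zero)))
  expect_true(all(is.finite(df$bic[df$converged])))
  expect_identical(path$selected, which(df$bic == min(df$bic))[1])
  expect_equal(df$bic, bic_value(-2 * df$loglik, df$df, 300))
  # a degenerate single-point grid at zero penalty returns the MLE
  p0 <- build_path_select_bic(dat, lambda1 = 0, lambda2 = 0,
                              control = list(tol = 1e-12, maxit = 2000))
  mle <- fit_unpenalized(dat, "zinb", se = FALSE,
                         control = list(tol = 1e-12, maxit = 2000))
  expect_lt(max(abs(p0$fit$beta - mle$beta)) / max(abs(mle$beta)), 1e-4)
  # the largest grid point nulls every penalized coefficient
  first <- path$coefficients[[1]]
  expect_true(all(first$beta[-1] == 0))
})

test_that("path coefficients vary continuously between support changes", {
  dat <- make_zinb_fixture(n = 400, seed = 59, h_total = 0.5)
  w <- adaptive_weights(dat)
  path <- build_path_select_bic(dat, w, nlambda1 = 40)
  B <- t(vapply(path$coefficients, function(cf) cf$beta, numeric(ncol(dat$X_count))))
  steps <- abs(diff(B))
  same_support <- vapply(seq_len(nrow(B) - 1), function(i)
    identical(which(B[i, ] != 0), which(B[i + 1, ] != 0)), logical(1))
  if (any(same_support))
    expect_lt(max(steps[same_support, ]), 0.35)
})

test_that("post-selection tests refit the support and respect the level", {
  dat <- make_zinb_fixture(n = 500, seed = 61, h_total = 0.6)
  path <- build_path_select_bic(dat, adaptive_weights(dat))
  ts <- post_selection_tests(path$fit, dat, alpha = 0.05)
  expect_identical(nrow(ts), ncol(dat$X_count) - 1L)
  expect_true(all(!ts$significant[!ts$selected]))
  expect_true(all(is.na(ts$p[!ts$selected])))
  if (any(ts$selected))
    expect_identical(ts$significant[ts$selected], ts$p[ts$selected] < 0.05)
  # empty support yields zero rejections
  big <- em_penalized_zinb(dat, 1e7, 1e7)
  ts0 <- post_selection_tests(big, dat)
  expect_false(any(ts0$significant))
  # |z| = 1 is below any conventional cutoff
  expect_gt(2 * pnorm(-1), 0.05)
})

test_that("unit weights reproduce the LASSO special case", {
  dat <- make_zinb_fixture(n = 300, seed = 67)
  uw <- unit_weights(dat)
  expect_true(all(uw$w1 == 1) && all(uw$w2 == 1))
  f1 <- em_penalized_zinb(dat, 4, 0, weights = uw)
  f2 <- em_penalized_zinb(dat, 4, 0, weights = penalty_spec(rep(1, 6), rep(1, 0)))
  expect_identical(f1$beta, f2$beta)
})
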