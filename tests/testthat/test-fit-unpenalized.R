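test_that("IWLS solves match closed-form maximum-likelihood estimates", {
  X <- matrix(1, 3, 1)
  f <- irls_glm_fit(X, c(0, 2, 4), "poisson")
  expect_equal(unname(f$coefficients), log(2), tolerance = 1e-8)
  # logistic with fractional responses all 0.5: intercept 0 by symmetry
  f2 <- irls_glm_fit(matrix(1, 10, 1), rep(0.5, 10), "binomial")
  expect_equal(unname(f2$coefficients), 0, tolerance = 1e-8)
  # constant prior weights leave the estimate unchanged
  dat <- make_zinb_fixture(n = 150, seed = 5)
  fa <- irls_glm_fit(dat$X_count, dat$y, "negbin", theta = 1)
  fb <- irls_glm_fit(dat$X_count, dat$y, "negbin", theta = 1,
                     prior_weights = rep(2.5, 150))
  expect_equal(fa$coefficients, fb$coefficients, tolerance = 1e-7)
})

test_that("EM fits are monotone in observed log-likelihood and nest correctly", {
  dat <- make_zinb_fixture(n = 300, seed = 7)
  fz <- fit_unpenalized(dat, "zinb")
  expect_true(fz$converged)
  expect_true(all(diff(fz$loglik_trace) > -1e-10))
  fp <- fit_unpenalized(dat, "zip")
  expect_true(all(diff(fp$loglik_trace) > -1e-10))
  # the richer mixture cannot fit worse than its count component
  fn <- fit_unpenalized(dat, "negbin")
  expect_gte(fz$loglik, fn$loglik - 1e-6)
  # reported loglik is the observed-data likelihood at the optimum
  expect_equal(fz$loglik, zinb_loglik(dat, fz$beta, fz$gamma, fz$theta))
})

test_that("datasets without zeros collapse the mixture onto the count model", {
  dat <- make_zinb_fixture(n = 200, seed = 11, zero_inflation = 0)
  dat$y <- dat$y + 1  # shift away any count-component zeros
  f <- fit_unpenalized(dat, "zinb")
  expect_match(f$note, "collapsed")
  expect_lt(plogis(f$gamma[1]), 1e-6)
  fn <- irls_glm_fit(dat$X_count, dat$y, "negbin", theta = 1)
  expect_equal(unname(f$beta), unname(fn$coefficients), tolerance = 1e-8)
})

test_that("analytic observed information matches a finite-difference Hessian", {
  skip_if_not_installed("pracma")
  dat <- make_zinb_fixture(n = 350, k = 4, seed = 13)
  for (fam in c("zinb", "zip")) {
    f <- fit_unpenalized(dat, fam)
    expect_true(f$converged)
    th <- if (fam == "zip") Inf else 1
    ll <- if (fam == "zip")
      function(par) zip_loglik(dat, par[1:5], par[6])
    else
      function(par) zinb_loglik(dat, par[1:5], par[6], 1)
    Hfd <- pracma::hessian(ll, c(f$beta, f$gamma))
    info <- zi_observed_info(dat$X_count, dat$X_zero, dat$y, f$beta, f$gamma, th)
    expect_lt(max(abs(-Hfd - info)) / max(abs(info)), 1e-5)
    se_fd <- sqrt(diag(solve(-Hfd)))
    expect_lt(max(abs(se_fd - c(f$se_beta, f$se_gamma)) / se_fd), 1e-3)
  }
})

test_that("theta can be profiled out during the ZINB EM", {
  des <- simulation_design(n = 1200, k = 4, maf = 0.3, causal_idx = 1:2,
                           h_total = 0.3, theta = 2)
  dat <- replicate_data(des, 17, 1)
  f <- fit_unpenalized(dat, "zinb", estimate_theta = TRUE, se = FALSE)
  expect_true(f$converged)
  expect_gt(f$theta, 0.8)
  expect_lt(f$theta, 6)
  # estimating theta cannot fit worse than fixing it at 1
  f1 <- fit_unpenalized(dat, "zinb", se = FALSE)
  expect_gte(f$loglik, f1$loglik - 1e-6)
})

test_that("wald_tests produces two-sided normal p-values on both components", {
  dat <- make_zinb_fixture(n = 400, seed = 19)
  f <- fit_unpenalized(dat, "zinb")
  wt <- wald_tests(f)
  expect_true(all(wt$p >= 0 & wt$p <= 1))
  expect_equal(wt$p, 2 * pnorm(-abs(wt$estimate / wt$se)))
  expect_identical(nrow(wt), length(f$beta) + length(f$gamma))
})
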