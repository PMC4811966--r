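#include <Rcpp.h>
using namespace Rcpp;

// Soft-thresholding kernel sign(z) * max(|z| - lam, 0)
inline double soft(double z, double lam) {
  if (z > lam) return z - lam;
  if (z < -lam) return z + lam;
  return 0.0;
}

static inline double clip_eta(double e) {
  if (e > 30.0) return 30.0;
  if (e < -30.0) return -30.0;
  return e;
}

// Penalized objective -2 * sum(obsw * loglik) + lambda * sum(pw_j |b_j|)
// family 0: NB(theta) log link (theta = R_PosInf gives Poisson)
// family 1: binomial logit link, fractional response allowed
static double pobj(const NumericMatrix &X, const NumericVector &y,
                   const NumericVector &obsw, int family, double theta,
                   double lambda, const NumericVector &pw,
                   const NumericVector &beta, const NumericVector &eta) {
  int n = X.nrow(), p = X.ncol();
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    if (obsw[i] <= 0) continue;
    double e = clip_eta(eta[i]);
    double li;
    if (family == 0) {
      if (theta == R_PosInf) {
        li = y[i] * e - std::exp(e); // Poisson kernel, constants dropped
      } else {
        li = y[i] * e - (y[i] + theta) * std::log(theta + std::exp(e));
      }
    } else {
      li = y[i] * e - std::log1p(std::exp(e));
      if (e > 0) li = y[i] * e - e - std::log1p(std::exp(-e));
    }
    ll += obsw[i] * li;
  }
  double pen = 0.0;
  for (int j = 0; j < p; ++j)
    if (R_finite(pw[j]) && pw[j] > 0 && beta[j] != 0)
      pen += pw[j] * std::fabs(beta[j]);
  return -2.0 * ll + lambda * pen;
}

// Coordinate-descent solve of a weighted penalized GLM on the IWLS
// quadratic approximation. X must include the intercept as column 0 with
// pw[0] = 0. Infinite pw entries exclude the coefficient (hard zero).
// [[Rcpp::export(name = ".cd_pglm_cpp")]]
List cd_pglm_cpp(NumericMatrix X, NumericVector y, NumericVector obsw,
                 int family, double theta, double lambda, NumericVector pw,
                 NumericVector start, double tol = 1e-9, int maxit_irls = 100,
                 int maxit_cd = 1000) {
  int n = X.nrow(), p = X.ncol();
  NumericVector beta = clone(start);
  // force excluded coefficients to zero before building eta
  for (int j = 0; j < p; ++j) if (!R_finite(pw[j]) && beta[j] != 0) beta[j] = 0.0;
  NumericVector eta(n), w(n), zw(n);
  for (int i = 0; i < n; ++i) {
    double e = 0.0;
    for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
    eta[i] = e;
  }
  double obj = pobj(X, y, obsw, family, theta, lambda, pw, beta, eta);
  bool converged = false;
  int it = 0;
  for (it = 0; it < maxit_irls; ++it) {
    // working weights and responses at current eta
    for (int i = 0; i < n; ++i) {
      double e = clip_eta(eta[i]);
      double l1, l2;
      if (family == 0) {
        double mu = std::exp(e);
        if (theta == R_PosInf) { l1 = y[i] - mu; l2 = mu; }
        else {
          double den = mu + theta;
          l1 = y[i] - (y[i] + theta) * mu / den;
          l2 = (y[i] + theta) * theta * mu / (den * den);
        }
      } else {
        double pr = 1.0 / (1.0 + std::exp(-e));
        l1 = y[i] - pr;
        l2 = pr * (1.0 - pr);
        if (l2 < 1e-5) l2 = 1e-5;
      }
      if (l2 < 1e-10) l2 = 1e-10;
      w[i] = obsw[i] * l2;
      zw[i] = eta[i] + l1 / l2; // working response
    }
    // residual r = z - eta and column curvatures
    NumericVector r(n), v(p);
    for (int i = 0; i < n; ++i) r[i] = zw[i] - eta[i];
    for (int j = 0; j < p; ++j) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += w[i] * X(i, j) * X(i, j);
      v[j] = s;
    }
    NumericVector beta_old = clone(beta);
    // one coordinate update; returns |change|
    auto update = [&](int j) -> double {
      if (!R_finite(pw[j]) || v[j] <= 0) return 0.0;
      double num = 0.0;
      for (int i = 0; i < n; ++i) num += w[i] * X(i, j) * r[i];
      num += v[j] * beta[j];
      double bj = (pw[j] > 0)
        ? soft(num, 0.5 * lambda * pw[j]) / v[j]
        : num / v[j];
      double d = bj - beta[j];
      if (d != 0.0) {
        for (int i = 0; i < n; ++i) r[i] -= X(i, j) * d;
        beta[j] = bj;
      }
      return std::fabs(d);
    };
    // full sweeps alternating with active-set iteration (glmnet-style)
    for (int outer = 0; outer < 10; ++outer) {
      double maxd = 0.0;
      for (int j = 0; j < p; ++j) maxd = std::max(maxd, update(j));
      if (maxd < tol) break;
      std::vector<int> active;
      for (int j = 0; j < p; ++j) if (beta[j] != 0.0) active.push_back(j);
      for (int cyc = 0; cyc < maxit_cd; ++cyc) {
        double md = 0.0;
        for (size_t a = 0; a < active.size(); ++a)
          md = std::max(md, update(active[a]));
        if (md < tol) break;
      }
    }
    for (int i = 0; i < n; ++i) eta[i] = zw[i] - r[i];
    double obj_new = pobj(X, y, obsw, family, theta, lambda, pw, beta, eta);
    // step halving if the quadratic step overshot the true objective
    int halv = 0;
    while (obj_new > obj + 1e-10 * (std::fabs(obj) + 1.0) && halv < 20) {
      for (int j = 0; j < p; ++j) beta[j] = 0.5 * (beta[j] + beta_old[j]);
      for (int i = 0; i < n; ++i) {
        double e = 0.0;
        for (int j = 0; j < p; ++j) if (beta[j] != 0.0) e += X(i, j) * beta[j];
        eta[i] = e;
      }
      obj_new = pobj(X, y, obsw, family, theta, lambda, pw, beta, eta);
      ++halv;
    }
    double maxch = 0.0;
    for (int j = 0; j < p; ++j) {
      double d = std::fabs(beta[j] - beta_old[j]);
      if (d > maxch) maxch = d;
    }
    bool obj_flat = std::fabs(obj - obj_new) < 1e-11 * (std::fabs(obj) + 1.0);
    obj = obj_new;
    if (maxch < 1e-8 || obj_flat) { converged = true; break; }
  }
  return List::create(_["beta"] = beta, _["objective"] = obj,
                      _["n_iter"] = it + 1, _["converged"] = converged,
                      _["eta"] = eta);
}
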