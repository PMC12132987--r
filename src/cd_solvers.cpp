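#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Soft-thresholding operator S(a, b) = sign(a) * max(|a| - b, 0).
inline double soft(double a, double b) {
  if (a > b) return a - b;
  if (a < -b) return a + b;
  return 0.0;
}

inline double clamp_eta(double eta) {
  if (eta > 30.0) return 30.0;
  if (eta < -30.0) return -30.0;
  return eta;
}

// Cyclic coordinate descent for the weighted penalized least-squares problem
//   min_beta  sum_i w_i (y_i - z_i' beta)^2 + lambda * sum_j pf_j |beta_j|
// pf_j = 0 leaves a coordinate (the intercept) unpenalized. The coordinate
// update is S(sum_i w_i z_ik r_i^(partial), lambda * pf_k / 2) / sum_i w_i z_ik^2,
// algebraically identical to the 2*numerator / 2*denominator form with
// threshold lambda * pf_k. A full residual vector is maintained incrementally.
// [[Rcpp::export]]
List cd_wls_lasso_cpp(NumericMatrix Z, NumericVector y, NumericVector w,
                      NumericVector beta_init, double lambda, NumericVector pf,
                      double tol, int max_iter) {
  const int n = Z.nrow(), p = Z.ncol();
  NumericVector beta = clone(beta_init);
  std::vector<double> r(n);
  for (int i = 0; i < n; ++i) {
    double eta = 0.0;
    for (int j = 0; j < p; ++j) eta += Z(i, j) * beta[j];
    r[i] = y[i] - eta;
  }
  std::vector<double> zz(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += w[i] * Z(i, j) * Z(i, j);
    zz[j] = s;
  }
  // One cyclic sweep over the coordinates listed in idx; returns the max
  // absolute coefficient change.
  auto sweep = [&](const std::vector<int>& idx) {
    double maxdel = 0.0;
    for (int j : idx) {
      if (zz[j] <= 0.0) continue;  // degenerate column: guarded in the R wrapper
      double num = 0.0;
      for (int i = 0; i < n; ++i) num += w[i] * Z(i, j) * r[i];
      num += zz[j] * beta[j];
      const double bnew = soft(num, 0.5 * lambda * pf[j]) / zz[j];
      const double del = bnew - beta[j];
      if (del != 0.0) {
        for (int i = 0; i < n; ++i) r[i] -= Z(i, j) * del;
        beta[j] = bnew;
        const double adel = std::fabs(del);
        if (adel > maxdel) maxdel = adel;
      }
    }
    return maxdel;
  };
  std::vector<int> all(p);
  for (int j = 0; j < p; ++j) all[j] = j;
  int it = 0;
  bool conv = false;
  // Full sweep, then iterate on the current active set until stable, then a
  // full sweep to verify no excluded coordinate re-enters (glmnet strategy).
  while (it < max_iter) {
    ++it;
    double maxdel = sweep(all);
    if (maxdel < tol) { conv = true; break; }
    std::vector<int> act;
    act.reserve(p);
    for (int j = 0; j < p; ++j) if (beta[j] != 0.0 || pf[j] == 0.0) act.push_back(j);
    while (it < max_iter) {
      ++it;
      if (sweep(act) < tol) break;
    }
  }
  return List::create(_["beta"] = beta, _["n_iter"] = it, _["converged"] = conv);
}

// Penalized objective of the logistic part on the working (doubled) scale:
//   O(beta) = 2 * sum_i [ln(1 + exp(eta_i)) - y_i eta_i] + lambda * sum_j pf_j |beta_j|
// The factor 2 matches the quadratic sum_i w_i (gamma_i - eta_i)^2 used by the
// inner loop, whose curvature is twice the negative log-likelihood's.
static double logistic_pen_obj(const NumericMatrix& Z, const NumericVector& y,
                               const NumericVector& beta, double lambda,
                               const NumericVector& pf) {
  const int n = Z.nrow(), p = Z.ncol();
  double obj = 0.0;
  for (int i = 0; i < n; ++i) {
    double eta = 0.0;
    for (int j = 0; j < p; ++j) eta += Z(i, j) * beta[j];
    eta = clamp_eta(eta);
    // stable log(1 + exp(eta))
    const double l1p = (eta > 0.0) ? eta + std::log1p(std::exp(-eta))
                                   : std::log1p(std::exp(eta));
    obj += 2.0 * (l1p - y[i] * eta);
  }
  for (int j = 0; j < p; ++j) obj += lambda * pf[j] * std::fabs(beta[j]);
  return obj;
}

// Nested IRLS + coordinate descent for the penalized logistic problem
//   min_beta  2 * [-l1(beta)] + lambda * sum_j pf_j |beta_j|.
// External loop: second-order (working response / weight) approximation at the
// current iterate, with weights w_i = p_i (1 - p_i) clamped below at w_min.
// Internal loop: cyclic coordinate descent on the penalized weighted least
// squares, with denominator sum_i w_i z_ik^2. A step-halving safeguard keeps
// the penalized objective non-increasing between outer iterates.
// [[Rcpp::export]]
List cd_logistic_lasso_cpp(NumericMatrix Z, NumericVector y,
                           NumericVector beta_init, double lambda,
                           NumericVector pf, double tol_outer, int max_outer,
                           double tol_inner, int max_inner, double w_min) {
  const int n = Z.nrow(), p = Z.ncol();
  NumericVector beta = clone(beta_init);
  NumericVector gamma(n), w(n);
  double obj = logistic_pen_obj(Z, y, beta, lambda, pf);
  int outer = 0;
  long inner_total = 0;
  bool conv = false;
  while (outer < max_outer) {
    ++outer;
    for (int i = 0; i < n; ++i) {
      double eta = 0.0;
      for (int j = 0; j < p; ++j) eta += Z(i, j) * beta[j];
      eta = clamp_eta(eta);
      const double pi = 1.0 / (1.0 + std::exp(-eta));
      double wi = pi * (1.0 - pi);
      if (wi < w_min) wi = w_min;
      w[i] = wi;
      gamma[i] = eta + (y[i] - pi) / wi;
    }
    List inner = cd_wls_lasso_cpp(Z, gamma, w, beta, lambda, pf, tol_inner, max_inner);
    NumericVector beta_new = inner["beta"];
    inner_total += as<int>(inner["n_iter"]);
    // step-halving on the true penalized objective
    double obj_new = logistic_pen_obj(Z, y, beta_new, lambda, pf);
    int halvings = 0;
    while (obj_new > obj + 1e-12 && halvings < 20) {
      for (int j = 0; j < p; ++j) beta_new[j] = 0.5 * (beta_new[j] + beta[j]);
      obj_new = logistic_pen_obj(Z, y, beta_new, lambda, pf);
      ++halvings;
    }
    double maxdel = 0.0;
    for (int j = 0; j < p; ++j) {
      const double d = std::fabs(beta_new[j] - beta[j]);
      if (d > maxdel) maxdel = d;
      beta[j] = beta_new[j];
    }
    obj = obj_new;
    if (maxdel < tol_outer) { conv = true; break; }
  }
  return List::create(_["beta"] = beta, _["n_outer"] = outer,
                      _["n_inner"] = (double)inner_total, _["converged"] = conv,
                      _["objective"] = obj);
}

// Warm-started coefficient path over a descending lambda grid, normal part.
// Rows of the returned matrix are the solutions at each lambda.
// [[Rcpp::export]]
NumericMatrix cd_wls_lasso_path_cpp(NumericMatrix Z, NumericVector y,
                                    NumericVector w, NumericVector lambdas,
                                    NumericVector pf, double tol, int max_iter) {
  const int p = Z.ncol(), L = lambdas.size();
  NumericMatrix out(L, p);
  NumericVector beta(p);
  for (int l = 0; l < L; ++l) {
    List res = cd_wls_lasso_cpp(Z, y, w, beta, lambdas[l], pf, tol, max_iter);
    NumericVector b = res["beta"];
    beta = b;
    for (int j = 0; j < p; ++j) out(l, j) = beta[j];
  }
  return out;
}

// Warm-started coefficient path over a descending lambda grid, binomial part.
// [[Rcpp::export]]
NumericMatrix cd_logistic_lasso_path_cpp(NumericMatrix Z, NumericVector y,
                                         NumericVector lambdas, NumericVector pf,
                                         double tol_outer, int max_outer,
                                         double tol_inner, int max_inner,
                                         double w_min) {
  const int p = Z.ncol(), L = lambdas.size();
  NumericMatrix out(L, p);
  NumericVector beta(p);
  for (int l = 0; l < L; ++l) {
    List res = cd_logistic_lasso_cpp(Z, y, beta, lambdas[l], pf, tol_outer,
                                     max_outer, tol_inner, max_inner, w_min);
    NumericVector b = res["beta"];
    beta = b;
    for (int j = 0; j < p; ++j) out(l, j) = beta[j];
  }
  return out;
}
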