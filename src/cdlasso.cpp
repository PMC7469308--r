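#include <Rcpp.h>
using namespace Rcpp;

// L1-penalized logistic regression by cyclic coordinate descent inside an
// IRLS (quadratic approximation) outer loop, glmnet-style.  Maximizes
//   (1/n) sum_i [ y_i eta_i - log(1 + exp(eta_i)) ] - lambda * sum_j |beta_j|
// with eta_i = beta0 + sum_j beta_j x_ij.  The intercept is never
// penalized.  X is expected column-standardized by the caller; columns
// flagged inactive (e.g. zero variance) are held at their initial value.

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// [[Rcpp::export]]
List cd_logistic_lasso(const NumericMatrix& X, const NumericVector& y,
                       double lambda, double beta0_init,
                       const NumericVector& beta_init,
                       const LogicalVector& active,
                       double tol, int max_iter) {
  const int n = X.nrow(), m = X.ncol();
  double beta0 = beta0_init;
  NumericVector beta = clone(beta_init);
  NumericVector eta(n), w(n), r(n), wx2(m);

  for (int i = 0; i < n; ++i) {
    double e = beta0;
    for (int j = 0; j < m; ++j) e += X(i, j) * beta[j];
    eta[i] = e;
  }

  bool converged = false;
  int outer = 0;
  for (outer = 0; outer < max_iter && !converged; ++outer) {
    // quadratic approximation at current eta
    double sw = 0.0;
    for (int i = 0; i < n; ++i) {
      double p = 1.0 / (1.0 + std::exp(-eta[i]));
      double wi = p * (1.0 - p);
      if (wi < 1e-9) wi = 1e-9;
      w[i] = wi;
      r[i] = y[i] - p;            // equals w * (z - eta)
      sw += wi;
    }
    for (int j = 0; j < m; ++j) {
      if (!active[j]) continue;
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += w[i] * X(i, j) * X(i, j);
      wx2[j] = s / n;
    }

    // inner CD on the weighted least-squares subproblem; r = w * (z - fit)
    for (int sweep = 0; sweep < 1000; ++sweep) {
      double max_delta = 0.0;
      double num0 = 0.0;
      for (int i = 0; i < n; ++i) num0 += r[i];
      double d0 = num0 / sw;
      if (d0 != 0.0) {
        beta0 += d0;
        for (int i = 0; i < n; ++i) r[i] -= w[i] * d0;
        max_delta = std::fabs(d0);
      }
      for (int j = 0; j < m; ++j) {
        if (!active[j]) continue;
        double g = 0.0;
        for (int i = 0; i < n; ++i) g += X(i, j) * r[i];
        double s = g / n + wx2[j] * beta[j];
        double bnew = soft(s, lambda) / wx2[j];
        double d = bnew - beta[j];
        if (d != 0.0) {
          beta[j] = bnew;
          for (int i = 0; i < n; ++i) r[i] -= w[i] * X(i, j) * d;
          if (std::fabs(d) > max_delta) max_delta = std::fabs(d);
        }
      }
      if (max_delta < tol * 0.1) break;
    }

    // refresh eta and test outer convergence on the linear predictor
    double max_eta_change = 0.0;
    for (int i = 0; i < n; ++i) {
      double e = beta0;
      for (int j = 0; j < m; ++j) e += X(i, j) * beta[j];
      if (std::fabs(e - eta[i]) > max_eta_change)
        max_eta_change = std::fabs(e - eta[i]);
      eta[i] = e;
    }
    if (max_eta_change < tol) converged = true;
  }

  return List::create(_["beta0"] = beta0, _["beta"] = beta,
                      _["iterations"] = outer,
                      _["converged"] = converged);
}
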