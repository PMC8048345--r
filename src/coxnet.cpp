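#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Score g and diagonal curvature w of the Cox partial log-likelihood with
// respect to the linear predictor eta, Breslow handling of ties.  Rows must
// arrive sorted by increasing follow-up time; tied times share a risk set.
// Returns the partial log-likelihood.
static double eta_stats(const NumericVector& time, const IntegerVector& status,
                        const std::vector<double>& eta,
                        std::vector<double>& g, std::vector<double>& w) {
  const int n = time.size();
  double m = eta[0];
  for (int i = 1; i < n; ++i) if (eta[i] > m) m = eta[i];
  std::vector<double> ex(n);
  std::vector<double> suffix(n + 1, 0.0);
  for (int i = n - 1; i >= 0; --i) {
    ex[i] = std::exp(eta[i] - m);
    suffix[i] = suffix[i + 1] + ex[i];
  }
  double cumA = 0.0, cumB = 0.0, ll = 0.0;
  int i = 0;
  while (i < n) {
    int j = i, d = 0;
    double ev_eta = 0.0;
    while (j < n && time[j] == time[i]) {
      if (status[j] == 1) { ++d; ev_eta += eta[j]; }
      ++j;
    }
    const double S0 = suffix[i];  // sum of exp(eta - m) over the risk set
    if (d > 0) {
      cumA += d / S0;
      cumB += d / (S0 * S0);
      ll += ev_eta - d * (std::log(S0) + m);
    }
    for (int k = i; k < j; ++k) {
      const double e = ex[k];
      g[k] = (status[k] == 1 ? 1.0 : 0.0) - e * cumA;
      w[k] = e * cumA - e * e * cumB;
      if (w[k] < 1e-12) w[k] = 1e-12;
    }
    i = j;
  }
  return ll;
}

// [[Rcpp::export]]
List cox_eta_stats_cpp(NumericVector time, IntegerVector status,
                       NumericVector eta) {
  const int n = time.size();
  std::vector<double> et(eta.begin(), eta.end()), g(n), w(n);
  double ll = eta_stats(time, status, et, g, w);
  return List::create(_["loglik"] = ll,
                      _["g"] = NumericVector(g.begin(), g.end()),
                      _["w"] = NumericVector(w.begin(), w.end()));
}

// Breslow partial log-likelihood for each column of a linear-predictor
// matrix (rows sorted by increasing time).
// [[Rcpp::export]]
NumericVector cox_loglik_path_cpp(NumericMatrix eta, NumericVector time,
                                  IntegerVector status) {
  const int n = eta.nrow(), L = eta.ncol();
  NumericVector ll(L);
  std::vector<double> et(n), g(n), w(n);
  for (int l = 0; l < L; ++l) {
    for (int i = 0; i < n; ++i) et[i] = eta(i, l);
    ll[l] = eta_stats(time, status, et, g, w);
  }
  return ll;
}

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// Elastic-net Cox along a decreasing lambda sequence with warm starts.
// Objective: -l(beta)/n + lambda * (alpha * ||beta||_1 + (1-alpha) * ||beta||_2^2),
// minimised by IRLS (diagonal curvature in eta) with cyclical coordinate
// descent on the penalized weighted least squares; after the coefficients
// stabilise the KKT conditions of the exact objective are verified and the
// outer loop continues until they hold within kkt_tol.
// X must be the (standardized) design sorted by increasing time.
// [[Rcpp::export]]
List coxnet_path_cpp(NumericMatrix X, NumericVector time, IntegerVector status,
                     double alpha, NumericVector lambdas, double tol,
                     int max_iter, NumericVector beta_init, double kkt_tol,
                     double dev_ratio_stop) {
  const int n = X.nrow(), p = X.ncol(), L = lambdas.size();
  const double* Xp = X.begin();   // column-major
  NumericMatrix betas(p, L);
  IntegerVector n_iter(L);
  LogicalVector converged(L);
  int n_fitted = 0;

  // null and saturated partial log-likelihoods for the saturation stop
  std::vector<double> eta0(n, 0.0), g0(n), w0(n);
  const double ll_null = eta_stats(time, status, eta0, g0, w0);
  double ll_sat = 0.0;
  {
    int i = 0;
    while (i < n) {
      int j = i, d = 0;
      while (j < n && time[j] == time[i]) { if (status[j] == 1) ++d; ++j; }
      if (d > 1) ll_sat -= d * std::log((double)d);
      i = j;
    }
  }

  std::vector<double> beta(beta_init.begin(), beta_init.end());
  std::vector<double> eta(n, 0.0), g(n), w(n), r(n), z(n), wx2(p);
  std::vector<int> active(p, 0);

  // starting eta from beta_init
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < p; ++j) if (beta[j] != 0.0) s += X(i, j) * beta[j];
    eta[i] = s;
  }

  double lam_prev = -1.0;
  for (int l = 0; l < L; ++l) {
    const double lam = lambdas[l];
    const double l1 = lam * alpha;
    const double l2 = 2.0 * lam * (1.0 - alpha);
    int sweeps = 0;
    bool ok = false;

    // sequential strong rule: screen to the coordinates whose gradient at
    // the warm start exceeds alpha * (2 * lam - lam_prev); violations are
    // caught by the exact KKT check below and re-screened.
    std::vector<char> strong(p, 0);
    {
      eta_stats(time, status, eta, g, w);
      const double cut = (lam_prev > 0.0)
        ? alpha * (2.0 * lam - lam_prev) : l1;
      for (int j = 0; j < p; ++j) {
        const double* xj = Xp + (size_t)j * n;
        double gr = 0.0;
        for (int i = 0; i < n; ++i) gr += xj[i] * g[i];
        gr = -gr / n;
        strong[j] = (beta[j] != 0.0 || std::fabs(gr) >= cut - kkt_tol);
      }
    }

    for (int outer = 0; outer < max_iter && !ok; ++outer) {
      eta_stats(time, status, eta, g, w);
      double sumw = 0.0;
      for (int i = 0; i < n; ++i) {
        r[i] = g[i] / w[i];          // residual of working response at current beta
        z[i] = eta[i] + r[i];
        sumw += w[i];
      }
      if (sumw <= 0) break;
      for (int j = 0; j < p; ++j) {
        if (!strong[j]) continue;
        const double* xj = Xp + (size_t)j * n;
        double s = 0.0;
        for (int i = 0; i < n; ++i) { const double x = xj[i]; s += w[i] * x * x; }
        wx2[j] = s / n;
      }

      // inner CD over the strong set: full strong sweep, then active-set
      // sweeps, then a confirming strong sweep
      double maxd_outer = 0.0;
      bool full_sweep = true;
      for (int pass = 0; pass < max_iter; ++pass) {
        double maxd = 0.0;
        for (int j = 0; j < p; ++j) {
          if (!strong[j]) continue;
          if (!full_sweep && !active[j]) continue;
          const double* xj = Xp + (size_t)j * n;
          double num = 0.0;
          for (int i = 0; i < n; ++i) num += w[i] * xj[i] * r[i];
          num = num / n + wx2[j] * beta[j];
          const double bnew = soft(num, l1) / (wx2[j] + l2);
          const double d = bnew - beta[j];
          if (d != 0.0) {
            for (int i = 0; i < n; ++i) r[i] -= xj[i] * d;
            beta[j] = bnew;
            // glmnet-style convergence scale: weighted squared change
            const double step = wx2[j] * d * d;
            if (step > maxd) maxd = step;
          }
          active[j] = (beta[j] != 0.0);
        }
        ++sweeps;
        if (maxd > maxd_outer) maxd_outer = maxd;
        if (maxd < tol) {
          if (full_sweep) break;       // converged on a full sweep
          full_sweep = true;           // confirm with a full sweep
        } else {
          full_sweep = false;
        }
        if (sweeps >= max_iter) break;
      }

      for (int i = 0; i < n; ++i) eta[i] = z[i] - r[i];

      if (maxd_outer < tol) {
        // exact-gradient KKT check over all coordinates
        eta_stats(time, status, eta, g, w);
        bool viol = false;
        for (int j = 0; j < p; ++j) {
          const double* xj = Xp + (size_t)j * n;
          double gr = 0.0;
          for (int i = 0; i < n; ++i) gr += xj[i] * g[i];
          gr = -gr / n;  // gradient of -l/n
          if (beta[j] == 0.0) {
            if (std::fabs(gr) > l1 + kkt_tol) {
              viol = true;
              strong[j] = 1;           // screened-out violator rejoins
            }
          } else {
            const double res = gr + l1 * (beta[j] > 0 ? 1.0 : -1.0) + l2 * beta[j];
            if (std::fabs(res) > kkt_tol) viol = true;
          }
        }
        if (!viol) ok = true;
      }
      if (sweeps >= max_iter) break;
    }
    lam_prev = lam;

    for (int j = 0; j < p; ++j) betas(j, l) = beta[j];
    n_iter[l] = sweeps;
    converged[l] = ok;
    n_fitted = l + 1;

    if (dev_ratio_stop < 1.0 && l + 1 < L) {
      const double ll = eta_stats(time, status, eta, g, w);
      const double denom = ll_sat - ll_null;
      if (denom > 0) {
        const double dev_ratio = (ll - ll_null) / denom;
        if (dev_ratio > dev_ratio_stop) break;   // model nearly saturated
      }
    }
  }

  return List::create(_["beta"] = betas, _["n_iter"] = n_iter,
                      _["converged"] = converged, _["n_fitted"] = n_fitted);
}
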