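#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double lse2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// log of the Global Alignment Kernel between two multivariate series
// (rows = time points, cols = variables), computed by the standard
// dynamic-programming recursion in log space.  Local kernel: the
// normalised Gaussian term exp(-phi) with
//   phi = d^2/(2 sigma^2) + log(2 - exp(-d^2/(2 sigma^2))),
// optionally multiplied by a triangular integer window of the given order
// (order 0 = unconstrained).
// [[Rcpp::export]]
double gak_logk_cpp(NumericMatrix xi, NumericMatrix xj, double sigma,
                    int window_order) {
  const int m = xi.nrow(), nn = xj.nrow(), p = xi.ncol();
  const double s2 = 2.0 * sigma * sigma;

  // log local kernel
  std::vector<double> lk((size_t)m * nn);
  for (int q = 0; q < m; ++q) {
    for (int r = 0; r < nn; ++r) {
      double d2 = 0.0;
      for (int a = 0; a < p; ++a) {
        const double d = xi(q, a) - xj(r, a);
        d2 += d * d;
      }
      const double u = d2 / s2;
      double v = -(u + std::log(2.0 - std::exp(-u)));
      if (window_order > 0) {
        const double tri = 1.0 - std::fabs((double)(q - r)) / window_order;
        v = (tri > 0.0) ? v + std::log(tri) : R_NegInf;
      }
      lk[(size_t)q * nn + r] = v;
    }
  }

  // DP over monotone alignments, log space; M has a padded border
  std::vector<double> prev(nn + 1, R_NegInf), cur(nn + 1, R_NegInf);
  prev[0] = 0.0;  // log M(0,0) = 0
  for (int q = 1; q <= m; ++q) {
    cur[0] = R_NegInf;
    for (int r = 1; r <= nn; ++r) {
      const double acc = lse2(lse2(prev[r], cur[r - 1]), prev[r - 1]);
      cur[r] = (acc == R_NegInf) ? R_NegInf
                                 : acc + lk[(size_t)(q - 1) * nn + (r - 1)];
    }
    std::swap(prev, cur);
  }
  return prev[nn];
}
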