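#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Action of the matrix exponential of the truncated CME generator on a
// probability vector, by uniformization. The generator is tridiagonal with
// birth rates b[a] (a -> a+1; b at the top state is zero, i.e. absorbing
// truncation) and death rates d[a] = gamma*a (a -> a-1). The time interval
// is split into segments with Lambda*tau_seg <= 64 so Poisson weights stay
// in double range; within each segment the series is truncated once the
// accumulated Poisson mass exceeds 1 - tol/n_seg, bounding the total
// truncation error by tol in the 1-norm.
// [[Rcpp::export]]
NumericVector fsp_propagate_cpp(NumericVector birth, NumericVector death,
                                NumericVector rho0, double tau, double tol) {
  int n = rho0.size();
  if (birth.size() != n || death.size() != n)
    stop("rate and state vectors must have equal length");
  if (tau < 0) stop("tau must be non-negative");
  std::vector<double> rho(rho0.begin(), rho0.end());
  if (tau == 0.0) return wrap(rho);

  double Lambda = 0.0;
  for (int i = 0; i < n; ++i) {
    double out = birth[i] + death[i];
    if (out > Lambda) Lambda = out;
  }
  if (Lambda <= 0.0) return wrap(rho);

  int n_seg = (int)std::ceil(Lambda * tau / 64.0);
  if (n_seg < 1) n_seg = 1;
  double tau_seg = tau / n_seg;
  double q = Lambda * tau_seg;
  double tol_seg = tol / n_seg;

  std::vector<double> v(n), w(n), res(n);
  for (int s = 0; s < n_seg; ++s) {
    // res = sum_m e^{-q} q^m/m! P^m rho,  P = I + B/Lambda
    double pw = std::exp(-q);
    double cum = pw;
    for (int i = 0; i < n; ++i) {
      v[i] = rho[i];
      res[i] = pw * rho[i];
    }
    int m = 0;
    while (cum < 1.0 - tol_seg) {
      ++m;
      // w = P v (tridiagonal substochastic transition)
      for (int i = 0; i < n; ++i) {
        double x = v[i] * (1.0 - (birth[i] + death[i]) / Lambda);
        if (i > 0) x += v[i - 1] * birth[i - 1] / Lambda;
        if (i < n - 1) x += v[i + 1] * death[i + 1] / Lambda;
        w[i] = x;
      }
      std::swap(v, w);
      pw *= q / m;
      cum += pw;
      for (int i = 0; i < n; ++i) res[i] += pw * v[i];
      if (m > 10 * (int)q + 1000) break;  // safety; series has converged long before
    }
    std::swap(rho, res);
  }
  // uniformization preserves non-negativity; clear tiny negative round-off
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rho[i] < 0 ? 0.0 : rho[i];
  return out;
}
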