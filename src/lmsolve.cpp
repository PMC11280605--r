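#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Batched damped (Levenberg-Marquardt) normal-equation solves: for each
// active pixel solve (JtJ + mu * diag(JtJ)) delta = -g by Gaussian
// elimination with partial pivoting on the small p x p system.
// JtJ: p*p*n array (column-major), g: n x p, mu: length n.
// Returns n x p matrix of steps; ok[i] = FALSE if the system was singular.
// [[Rcpp::export]]
List damped_solve_batch(NumericVector JtJ, NumericMatrix g,
                        NumericVector mu, LogicalVector active) {
  const int n = g.nrow(), p = g.ncol();
  NumericMatrix delta(n, p);
  LogicalVector ok(n, true);
  std::vector<double> A(p * p), b(p);
  for (int px = 0; px < n; ++px) {
    if (!active[px]) continue;
    const double* base = &JtJ[(size_t)px * p * p];
    for (int c = 0; c < p; ++c)
      for (int r = 0; r < p; ++r)
        A[c * p + r] = base[c * p + r];
    for (int d = 0; d < p; ++d) {
      double dd = A[d * p + d];
      if (dd < 1e-12) dd = 1e-12;
      A[d * p + d] += mu[px] * dd;
    }
    for (int r = 0; r < p; ++r) b[r] = -g(px, r);
    // Gaussian elimination with partial pivoting
    bool fail = false;
    for (int c = 0; c < p && !fail; ++c) {
      int piv = c;
      double amax = std::fabs(A[c * p + c]);
      for (int r = c + 1; r < p; ++r) {
        double v = std::fabs(A[c * p + r]);
        if (v > amax) { amax = v; piv = r; }
      }
      if (amax < 1e-300) { fail = true; break; }
      if (piv != c) {
        for (int cc = c; cc < p; ++cc)
          std::swap(A[cc * p + c], A[cc * p + piv]);
        std::swap(b[c], b[piv]);
      }
      for (int r = c + 1; r < p; ++r) {
        double f = A[c * p + r] / A[c * p + c];
        if (f == 0.0) continue;
        for (int cc = c + 1; cc < p; ++cc)
          A[cc * p + r] -= f * A[cc * p + c];
        b[r] -= f * b[c];
      }
    }
    if (fail) { ok[px] = false; continue; }
    for (int r = p - 1; r >= 0; --r) {
      double s = b[r];
      for (int cc = r + 1; cc < p; ++cc)
        s -= A[cc * p + r] * delta(px, cc);
      delta(px, r) = s / A[r * p + r];
    }
  }
  return List::create(_["delta"] = delta, _["ok"] = ok);
}
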