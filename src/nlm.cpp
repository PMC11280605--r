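#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Non-local means with replicate boundary handling. d2 is the mean squared
// difference between the (2pr+1)^2 patches around the target and candidate
// pixels; weights exp(-max(d2 - 2*lambda, 0)/lambda) with the self weight
// set to the maximum neighbour weight (standard NLM practice).
// [[Rcpp::export]]
NumericMatrix nlm_denoise_cpp(NumericMatrix img, double lambda,
                              int patch_radius, int search_radius) {
  const int n1 = img.nrow(), n2 = img.ncol();
  const int pr = patch_radius, sr = search_radius;
  NumericMatrix out(n1, n2);
  const double h2 = lambda;
  const int pn = (2 * pr + 1) * (2 * pr + 1);
  auto at = [&](int i, int j) -> double {
    if (i < 0) i = 0; else if (i >= n1) i = n1 - 1;
    if (j < 0) j = 0; else if (j >= n2) j = n2 - 1;
    return img(i, j);
  };
  for (int i = 0; i < n1; ++i) {
    for (int j = 0; j < n2; ++j) {
      double wsum = 0.0, acc = 0.0, wmax = 0.0;
      for (int si = i - sr; si <= i + sr; ++si) {
        for (int sj = j - sr; sj <= j + sr; ++sj) {
          if (si == i && sj == j) continue;
          double d2 = 0.0;
          for (int pi = -pr; pi <= pr; ++pi)
            for (int pj = -pr; pj <= pr; ++pj) {
              double diff = at(i + pi, j + pj) - at(si + pi, sj + pj);
              d2 += diff * diff;
            }
          d2 /= pn;
          double ex = d2 - 2.0 * lambda;
          double w = ex <= 0.0 ? 1.0 : std::exp(-ex / h2);
          if (w > wmax) wmax = w;
          wsum += w;
          acc += w * at(si, sj);
        }
      }
      double wself = wmax > 0.0 ? wmax : 1.0;
      out(i, j) = (acc + wself * img(i, j)) / (wsum + wself);
    }
  }
  return out;
}
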