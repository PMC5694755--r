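#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exponential-kernel sums: for each row c of `eval` (B x d), compute
//   sum_j w_j * exp(-||c - y_j|| / h)
// over the rows y_j of `points` (n x d). Used both for gridded density
// estimation (eval = bin centres) and for held-out likelihood in bandwidth
// cross-validation (eval = held-out points).
// [[Rcpp::export(name = ".kernel_sum_cpp")]]
NumericVector kernel_sum_cpp(NumericMatrix eval, NumericMatrix points,
                             NumericVector weights, double h) {
  const int B = eval.nrow(), n = points.nrow(), d = eval.ncol();
  NumericVector out(B);
  for (int b = 0; b < B; ++b) {
    double acc = 0.0;
    for (int j = 0; j < n; ++j) {
      double r2 = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = eval(b, k) - points(j, k);
        r2 += diff * diff;
      }
      acc += weights[j] * std::exp(-std::sqrt(r2) / h);
    }
    out[b] = acc;
  }
  return out;
}
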