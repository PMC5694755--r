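#include <Rcpp.h>
using namespace Rcpp;

// Gotoh affine-gap local alignment, scores only (no traceback).
//
// Gap conventions:
//   first_residue_full_open = true  (default): a gap of length L costs
//       open + (L - 1) * extend   (the striped-SW / parasail convention)
//   first_residue_full_open = false: a gap of length L costs
//       open + L * extend
//
// `a` and `b` are 0-based integer encodings into the substitution matrix.
static int sw_score_one(const IntegerVector& a, const IntegerVector& b,
                        const IntegerMatrix& sub, int open, int extend,
                        bool first_full) {
  const int n = a.size(), m = b.size();
  const int open1 = first_full ? open : open + extend;  // cost of a length-1 gap
  const int NEG = INT_MIN / 4;
  std::vector<int> H(m + 1, 0);   // H[i-1][*] rolling into H[i][*]
  std::vector<int> E(m + 1, NEG); // gap-in-a state, column-wise
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    int prev_diag = 0;  // H[i-1][j-1]
    int left = 0;       // H[i][j-1]
    int F = NEG;        // gap-in-b state along the row
    for (int j = 1; j <= m; ++j) {
      E[j] = std::max(H[j] - open1, E[j] - extend);
      F    = std::max(left - open1, F - extend);
      int h = prev_diag + sub(a[i - 1], b[j - 1]);
      h = std::max(h, E[j]);
      h = std::max(h, F);
      h = std::max(h, 0);
      prev_diag = H[j];
      H[j] = h;
      left = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".sw_score_cpp")]]
int sw_score_cpp(IntegerVector a, IntegerVector b, IntegerMatrix sub,
                 int gap_open, int gap_extend, bool first_residue_full_open) {
  return sw_score_one(a, b, sub, gap_open, gap_extend, first_residue_full_open);
}

// Full symmetric score matrix (upper triangle computed, mirrored).
// seqs: list of 0-based integer vectors.
// [[Rcpp::export(name = ".sw_matrix_cpp")]]
NumericMatrix sw_matrix_cpp(List seqs, IntegerMatrix sub,
                            int gap_open, int gap_extend,
                            bool first_residue_full_open) {
  const int n = seqs.size();
  std::vector<IntegerVector> enc(n);
  for (int i = 0; i < n; ++i) enc[i] = as<IntegerVector>(seqs[i]);
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      int s = sw_score_one(enc[i], enc[j], sub, gap_open, gap_extend,
                           first_residue_full_open);
      D(i, j) = s;
      D(j, i) = s;
    }
    Rcpp::checkUserInterrupt();
  }
  return D;
}
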