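#include <Rcpp.h>
using namespace Rcpp;

// Weighted double sum over all index pairs: sum_ij |a_i - b_j|^p * w_ij.
// p == 1 avoids pow(); this inner loop dominates the leave-one-out lambda
// search (n = 168 gives ~28k terms per evaluation).
// [[Rcpp::export]]
double dima_cross_sum(NumericVector a, NumericVector b, NumericMatrix w,
                      double p = 1.0) {
  int n = a.size();
  double acc = 0.0;
  if (p == 1.0) {
    for (int j = 0; j < n; ++j) {
      double bj = b[j];
      for (int i = 0; i < n; ++i) {
        double wij = w(i, j);
        if (wij != 0.0) acc += std::abs(a[i] - bj) * wij;
      }
    }
  } else {
    for (int j = 0; j < n; ++j) {
      double bj = b[j];
      for (int i = 0; i < n; ++i) {
        double wij = w(i, j);
        if (wij != 0.0) acc += std::pow(std::abs(a[i] - bj), p) * wij;
      }
    }
  }
  return acc;
}

// Batched version: rows of x against a fixed series b (e.g. a class
// centroid), one cross-sum per row.
// [[Rcpp::export]]
NumericVector dima_cross_sum_rows(NumericMatrix x, NumericVector b,
                                  NumericMatrix w) {
  int m = x.nrow(), n = b.size();
  NumericVector out(m);
  for (int r = 0; r < m; ++r) {
    double acc = 0.0;
    for (int j = 0; j < n; ++j) {
      double bj = b[j];
      for (int i = 0; i < n; ++i) {
        double wij = w(i, j);
        if (wij != 0.0) acc += std::abs(x(r, i) - bj) * wij;
      }
    }
    out[r] = acc;
  }
  return out;
}
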