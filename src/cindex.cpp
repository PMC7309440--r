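#include <Rcpp.h>
using namespace Rcpp;

// Pair-counting concordance: usable pairs have unequal outcomes; a pair is
// concordant when prediction and outcome differences share a sign; tied
// predictions on a usable pair earn half credit.
// [[Rcpp::export(name = ".cindex_pairs")]]
double cindex_pairs(NumericVector pred, NumericVector outcome) {
  const R_xlen_t n = pred.size();
  double concordant = 0.0;
  double usable = 0.0;
  for (R_xlen_t i = 0; i < n - 1; ++i) {
    for (R_xlen_t j = i + 1; j < n; ++j) {
      const double dy = outcome[i] - outcome[j];
      if (dy == 0.0) continue;
      usable += 1.0;
      const double dp = pred[i] - pred[j];
      if (dp == 0.0) {
        concordant += 0.5;
      } else if (dp * dy > 0.0) {
        concordant += 1.0;
      }
    }
  }
  if (usable == 0.0) return NA_REAL;
  return concordant / usable;
}
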