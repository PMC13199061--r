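#include <Rcpp.h>
using namespace Rcpp;

// Harrell pair counts. A pair (i, j) is comparable when T_i < T_j and
// patient i experienced the event; equal-time pairs are never comparable
// (tied event times carry no ordering information under this convention).
// Equal risks in a comparable pair count one half.
// [[Rcpp::export(name = ".concordance_counts")]]
NumericVector concordance_counts(NumericVector time, IntegerVector event,
                                 NumericVector risk) {
  const int n = time.size();
  double conc = 0.0, tied = 0.0, comp = 0.0;
  for (int i = 0; i < n; ++i) {
    if (event[i] != 1) continue;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (time[i] < time[j]) {
        comp += 1.0;
        if (risk[i] > risk[j]) conc += 1.0;
        else if (risk[i] == risk[j]) tied += 1.0;
      }
    }
  }
  return NumericVector::create(conc, tied, comp);
}

// bootstrap helper: one c-index per column of a 1-based resample index
// matrix; NA when a replicate has no comparable pairs
// [[Rcpp::export(name = ".concordance_boot")]]
NumericVector concordance_boot(NumericVector time, IntegerVector event,
                               NumericVector risk, IntegerMatrix idx) {
  const int n = idx.nrow(), B = idx.ncol();
  NumericVector out(B);
  std::vector<double> t(n), r(n);
  std::vector<int> e(n);
  for (int b = 0; b < B; ++b) {
    for (int k = 0; k < n; ++k) {
      int j = idx(k, b) - 1;
      t[k] = time[j]; e[k] = event[j]; r[k] = risk[j];
    }
    double conc = 0.0, tied = 0.0, comp = 0.0;
    for (int i = 0; i < n; ++i) {
      if (e[i] != 1) continue;
      for (int j = 0; j < n; ++j) {
        if (t[i] < t[j]) {
          comp += 1.0;
          if (r[i] > r[j]) conc += 1.0;
          else if (r[i] == r[j]) tied += 1.0;
        }
      }
    }
    out[b] = comp > 0 ? (conc + 0.5 * tied) / comp : NA_REAL;
  }
  return out;
}
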