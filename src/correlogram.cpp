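#include <Rcpp.h>
using namespace Rcpp;

// Binned counts of ordered spike-time delays t_j - t_i in [0, max_lag),
// bins of width bin_s. Both trains must be sorted ascending.
// Two-pointer sweep: O(n_i + n_j + n_delays).
// [[Rcpp::export]]
IntegerVector delay_bin_counts(NumericVector ti, NumericVector tj,
                               double max_lag, double bin_s) {
  int nbins = (int)std::ceil(max_lag / bin_s - 1e-9);
  if (nbins < 1) nbins = 1;
  IntegerVector counts(nbins);
  int ni = ti.size(), nj = tj.size();
  int lo = 0;
  for (int a = 0; a < ni; ++a) {
    while (lo < nj && tj[lo] < ti[a]) ++lo;
    for (int b = lo; b < nj; ++b) {
      double d = tj[b] - ti[a];
      if (d >= max_lag) break;
      int k = (int)(d / bin_s);
      if (k >= nbins) k = nbins - 1;
      counts[k]++;
    }
  }
  return counts;
}
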