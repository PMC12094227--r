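#include <Rcpp.h>
using namespace Rcpp;

// Cross-correlogram pair counts. For every (pre, post) spike pair with
// lag = post - pre in [-window, window], increments the bin containing the
// lag. Bins are centred on multiples of bin_s: bin i covers
// [(i - nb - 0.5) * bin_s, (i - nb + 0.5) * bin_s). Both trains must be
// sorted ascending.
// [[Rcpp::export]]
IntegerVector ccg_count(NumericVector pre, NumericVector post,
                        double bin_s, double window_s) {
  int nb = (int)std::floor(window_s / bin_s + 0.5);
  IntegerVector counts(2 * nb + 1);
  int np = post.size();
  int lo = 0;
  for (int i = 0; i < pre.size(); ++i) {
    double t0 = pre[i] - window_s - 0.5 * bin_s;
    double t1 = pre[i] + window_s + 0.5 * bin_s;
    while (lo < np && post[lo] < t0) ++lo;
    for (int j = lo; j < np && post[j] < t1; ++j) {
      int b = (int)std::floor((post[j] - pre[i]) / bin_s + 0.5) + nb;
      if (b >= 0 && b <= 2 * nb) ++counts[b];
    }
  }
  return counts;
}
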