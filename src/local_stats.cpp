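#include <Rcpp.h>
using namespace Rcpp;

// Sliding-window sum and sum of squares with edge-replicated borders.
// Pixel intensities are integer-valued, so both accumulators are exact in
// doubles (largest case: 17x17 window of 16-bit values < 2^53) and any
// reimplementation summing the same window contents gets identical local
// means and variances.
//
// [[Rcpp::export]]
List cc_local_sums(NumericMatrix img, int radius, bool circular) {
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<int> di, dj;
  di.reserve((2 * radius + 1) * (2 * radius + 1));
  dj.reserve((2 * radius + 1) * (2 * radius + 1));
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      if (!circular || a * a + b * b <= radius * radius) {
        di.push_back(a);
        dj.push_back(b);
      }
  const int m = (int) di.size();
  NumericMatrix s(nr, nc), ss(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0, acc2 = 0.0;
      for (int t = 0; t < m; ++t) {
        int ii = i + di[t];
        if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
        int jj = j + dj[t];
        if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;
        const double v = img(ii, jj);
        acc += v;
        acc2 += v * v;
      }
      s(i, j) = acc;
      ss(i, j) = acc2;
    }
  }
  return List::create(_["sum"] = s, _["sumsq"] = ss, _["n"] = m);
}
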