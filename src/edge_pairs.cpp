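#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Accumulate the second-order edge-pair histogram.
//
// For every unordered pair (i, j), i < j, the pair is binned by Euclidean
// distance d (nd bins spanning (0, d_max]) and by the pairwise angle alpha
// (na bins over 0-360 degrees of polarity-extended direction difference,
// taken as theta_i - theta_j modulo 360 in the stored edge order). The
// product of the two intensities is added to the orientation histograms of
// both pair members (no orientation bins, modulo 180) within that
// (d, alpha) cell.
//
// Returns a numeric vector of length nd * na * no laid out in column-major
// order, i.e. index d + nd * (a + na * o).
// [[Rcpp::export]]
NumericVector edge_pair_hist_cpp(NumericVector x, NumericVector y,
                                 NumericVector theta_deg,
                                 IntegerVector ori0, NumericVector intensity,
                                 int nd, int na, int no, double d_max) {
  const int n = x.size();
  NumericVector out((R_xlen_t)nd * na * no);
  const double dbin = d_max / nd;
  const double abin = 360.0 / na;
  for (int i = 0; i < n - 1; ++i) {
    const double xi = x[i], yi = y[i], ti = theta_deg[i], wi = intensity[i];
    const int oi = ori0[i];
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[j] - xi, dy = y[j] - yi;
      double d = std::sqrt(dx * dx + dy * dy);
      int db = (int)std::ceil(d / dbin) - 1;
      if (db < 0) db = 0;
      if (db >= nd) db = nd - 1;
      double alpha = ti - theta_deg[j];
      alpha -= 360.0 * std::floor(alpha / 360.0);
      int ab = (int)std::floor(alpha / abin);
      if (ab >= na) ab = na - 1;
      const double w = wi * intensity[j];
      out[db + (R_xlen_t)nd * (ab + (R_xlen_t)na * oi)] += w;
      out[db + (R_xlen_t)nd * (ab + (R_xlen_t)na * ori0[j])] += w;
    }
  }
  return out;
}
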