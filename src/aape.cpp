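#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Weighted ordinal-pattern entropy for many series at once.
//
// Each row of X is one time series. For every window of m consecutive
// samples the stable ordinal rank of each sample is computed (ties broken
// by earlier time offset), the window is assigned a pattern code, and the
// window's weight K*AA + (1-K)*RA (AA = mean |x|, RA = mean |successive
// difference|) is accumulated on that code. With weighted = false every
// window gets weight 1, giving plain permutation entropy. Entropy is the
// Shannon entropy (nats) of the normalized weights.
//
// A series whose total weight is exactly zero (identically-zero input) is
// degenerate: entropy 0, flagged in the second list element.
// [[Rcpp::export(name = ".aape_engine")]]
List aape_engine(NumericMatrix X, int m, double K, bool weighted) {
  const int nser = X.nrow(), N = X.ncol();
  if (m < 2) stop("m must be >= 2");
  if (N < m) stop("series length (%d) must be >= m (%d)", N, m);
  const int nwin = N - m + 1;

  // pattern code = sum_j rank_j * m^j, table size m^m
  std::vector<double> powm(m);
  double tbl = 1.0;
  for (int j = 0; j < m; ++j) { powm[j] = tbl; tbl *= m; }
  const size_t tblsize = (size_t) tbl;
  std::vector<double> acc(tblsize, 0.0);
  std::vector<int> touched;
  touched.reserve(nwin < 5040 ? nwin : 5040);

  NumericVector ent(nser);
  LogicalVector degen(nser);
  std::vector<double> v(m);

  for (int s = 0; s < nser; ++s) {
    touched.clear();
    double total = 0.0;
    for (int i = 0; i < nwin; ++i) {
      double aa = 0.0, ra = 0.0;
      for (int j = 0; j < m; ++j) {
        v[j] = X(s, i + j);
        if (!R_finite(v[j]))
          stop("non-finite value at series %d, index %d", s + 1, i + j + 1);
        aa += std::fabs(v[j]);
        if (j > 0) ra += std::fabs(v[j] - v[j - 1]);
      }
      double w = 1.0;
      if (weighted) w = K * (aa / m) + (1.0 - K) * (ra / (m - 1));
      // stable rank: smaller value first, earlier offset first on ties
      int code = 0;
      for (int j = 0; j < m; ++j) {
        int r = 0;
        for (int k = 0; k < m; ++k) {
          if (v[k] < v[j] || (v[k] == v[j] && k < j)) ++r;
        }
        code += (int) (r * powm[j]);
      }
      if (acc[code] == 0.0) touched.push_back(code);
      acc[code] += w;
      total += w;
    }
    double h = 0.0;
    if (total <= 0.0) {
      degen[s] = true;
    } else {
      for (size_t t = 0; t < touched.size(); ++t) {
        double p = acc[touched[t]] / total;
        if (p > 0.0) h -= p * std::log(p);
      }
    }
    ent[s] = h;
    for (size_t t = 0; t < touched.size(); ++t) acc[touched[t]] = 0.0;
  }
  return List::create(_["entropy"] = ent, _["degenerate"] = degen);
}
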