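#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Feasibility kernel for the dip statistic.
//
// A monotone convex (or concave) CDF branch must pass, at positions t_i,
// through the interval constraints [L_i - eps, U_i + eps]. Such a branch
// exists iff eps >= max_i violation_i / 2 where, for the convex branch,
// violation_i = L_i - gcm(U)(t_i) with gcm the greatest convex minorant
// (lower convex hull) of the points (t_i, U_i); for the concave branch,
// violation_i = lcm(L)(t_i) - U_i with lcm the least concave majorant.
// This function returns max_i violation_i (not halved).
//
// t must be strictly increasing.

// [[Rcpp::export(name = ".dip_band_violation")]]
double dip_band_violation(NumericVector t, NumericVector U, NumericVector L,
                          bool convex) {
  const int n = t.size();
  if (n == 0) return 0.0;
  std::vector<double> y(n);
  for (int i = 0; i < n; ++i) y[i] = convex ? U[i] : -L[i];

  // lower convex hull of (t, y), monotone chain
  std::vector<int> h;
  h.reserve(n);
  for (int i = 0; i < n; ++i) {
    while (h.size() >= 2) {
      int a = h[h.size() - 2], b = h[h.size() - 1];
      double cross = (t[b] - t[a]) * (y[i] - y[a]) -
                     (y[b] - y[a]) * (t[i] - t[a]);
      if (cross <= 0.0) h.pop_back(); else break;
    }
    h.push_back(i);
  }

  double worst = 0.0;
  int seg = 0;
  const int nh = (int) h.size();
  for (int i = 0; i < n; ++i) {
    while (seg + 1 < nh && t[h[seg + 1]] <= t[i]) ++seg;
    double hv;
    int a = h[seg];
    if (seg + 1 >= nh || t[i] <= t[a]) {
      hv = y[a];
    } else {
      int b = h[seg + 1];
      hv = y[a] + (y[b] - y[a]) * (t[i] - t[a]) / (t[b] - t[a]);
    }
    double viol = convex ? (L[i] - hv) : ((-hv) - U[i]);
    if (viol > worst) worst = viol;
  }
  return worst;
}
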