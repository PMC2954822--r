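#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive affine-gap alignment scoring by depth-first enumeration of
// monotone alignment paths. No dynamic-programming table is kept: every
// path is walked independently, so the cost is exponential in sequence
// length. This is the independent reference against which the DP route
// (alignPair) is validated on short sequences.
//
// state: 0 = last column was a substitution (or start), 1 = gap in a,
// 2 = gap in b. A gap of length L costs open + L * ext.

static double dfs_global(const IntegerVector& a, const IntegerVector& b,
                         const NumericMatrix& S, double open, double ext,
                         int i, int j, int state) {
  const int la = a.size(), lb = b.size();
  if (i == la && j == lb) return 0.0;
  double best = R_NegInf;
  if (i < la && j < lb) {
    double s = S(a[i], b[j]) +
      dfs_global(a, b, S, open, ext, i + 1, j + 1, 0);
    if (s > best) best = s;
  }
  if (j < lb) { // gap in a, consumes b[j]
    double cost = (state == 1) ? ext : open + ext;
    double s = -cost + dfs_global(a, b, S, open, ext, i, j + 1, 1);
    if (s > best) best = s;
  }
  if (i < la) { // gap in b, consumes a[i]
    double cost = (state == 2) ? ext : open + ext;
    double s = -cost + dfs_global(a, b, S, open, ext, i + 1, j, 2);
    if (s > best) best = s;
  }
  return best;
}

// [[Rcpp::export]]
double brute_align(IntegerVector a, IntegerVector b, NumericMatrix S,
                   double open, double ext, bool local) {
  if (!local)
    return dfs_global(a, b, S, open, ext, 0, 0, 0);
  // Local optimum = best global-style score over all substring pairs
  // (an optimal local alignment begins and ends with a substitution
  // column, so end-gapped variants are dominated), floored at 0.
  double best = 0.0;
  const int la = a.size(), lb = b.size();
  for (int i1 = 0; i1 < la; ++i1)
    for (int i2 = i1; i2 < la; ++i2)
      for (int j1 = 0; j1 < lb; ++j1)
        for (int j2 = j1; j2 < lb; ++j2) {
          IntegerVector sa(a.begin() + i1, a.begin() + i2 + 1);
          IntegerVector sb(b.begin() + j1, b.begin() + j2 + 1);
          double s = dfs_global(sa, sb, S, open, ext, 0, 0, 0);
          if (s > best) best = s;
        }
  return best;
}
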