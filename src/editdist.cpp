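#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static const int BIGD = 1000000000;

// Banded prefix edit distance machinery (Ukkonen-style band of half-width B
// around the main diagonal). The DP is row-per-query-character so that the
// state can be extended incrementally during a graph DFS and rolled back by
// keeping the previous state on the stack.
//
// Conventions: target xi (length l) indexes columns j = 0..l; query xi_n
// indexes rows q. Row storage is a window row[off], off = 0..2B, holding
// D[q][j] with j = q + off - B.
//
// Reported quantities for the current row q:
//   dmin  = min_j D[q][j]            (prefix edit distance, trailing target
//                                     bases ignored)
//   jstar = largest argmin_j          (g = l - jstar trailing insertions)
//   e     = min( min_j D[q][j]+(l-j), min_{i<=q} D[i][l] )
//           i.e. the overlap-alignment distance: either the target has a
//           trailing overhang (counted in full) or the query does (free).

// [[Rcpp::export]]
List cpp_band_init(int l, int B) {
  NumericVector row(2 * B + 1, (double)BIGD);
  for (int j = 0; j <= std::min(B, l); ++j) row[j + B] = j;
  double colmin = (l <= B) ? (double)l : (double)BIGD;
  return List::create(_["row"] = row, _["q"] = 0, _["l"] = l, _["B"] = B,
                      _["colmin"] = colmin);
}

// [[Rcpp::export]]
List cpp_band_extend(List state, std::string target, std::string add) {
  NumericVector row0 = state["row"];
  int q = state["q"];
  int l = state["l"];
  int B = state["B"];
  double colmin = state["colmin"];
  int W = 2 * B + 1;
  std::vector<double> prev(row0.begin(), row0.end()), cur((size_t)W);

  for (size_t t = 0; t < add.size(); ++t) {
    char c = add[t];
    ++q;
    for (int off = 0; off < W; ++off) {
      int j = q + off - B;
      if (j < 0 || j > l) { cur[(size_t)off] = BIGD; continue; }
      double best = BIGD;
      // deletion of query char: D[q-1][j] + 1, prev off = off + 1
      if (off + 1 < W) best = std::min(best, prev[(size_t)off + 1] + 1);
      // insertion of target char: D[q][j-1] + 1, same row off - 1
      if (off - 1 >= 0 && cur[(size_t)off - 1] + 1 < best) best = cur[(size_t)off - 1] + 1;
      // match / substitution: D[q-1][j-1], prev off = off
      if (j >= 1) {
        double d = prev[(size_t)off] + ((target[(size_t)j - 1] == c) ? 0 : 1);
        if (d < best) best = d;
      }
      cur[(size_t)off] = best;
    }
    int offl = l - q + B;
    if (offl >= 0 && offl < W && cur[(size_t)offl] < colmin) colmin = cur[(size_t)offl];
    prev = cur;
  }

  // dmin: prefix edit distance (min over the row; trailing target bases
  // free). erow: overlap distance min_j D[q][j] + (l - j); jstar is its
  // smallest minimiser, so that (d, g) = (D[q][jstar], l - jstar) describes
  // the alignment with the fewest edits and the rest of the target as
  // trailing insertions, and d + g equals the full Levenshtein distance
  // whenever the query consumes the target.
  double dmin = BIGD, erow = BIGD;
  int jstar = -1;
  for (int off = 0; off < W; ++off) {
    int j = q + off - B;
    if (j < 0 || j > l) continue;
    double d = prev[(size_t)off];
    if (d < dmin) dmin = d;
    if (d + (l - j) < erow) { erow = d + (l - j); jstar = j; }
  }
  double e = std::min(erow, colmin);
  NumericVector row(prev.begin(), prev.end());
  return List::create(_["row"] = row, _["q"] = q, _["l"] = l, _["B"] = B,
                      _["colmin"] = colmin, _["dmin"] = dmin,
                      _["jstar"] = jstar, _["e"] = e, _["erow"] = erow);
}

// ---- brute-force integer edge-visit search ---------------------------------

// Minimise sum_z ( |c_z - t_{z-}|/2 + |c_z - t_{z+}|/2 + |t_{z-} - t_{z+}| ) *
// log(l_z) over integer edge visit counts t_e in [lo_e, hi_e]. Each edge e is
// incident to two node sides given in `sa` and `sb` (1-based side ids); sides
// 2z-1 / 2z are the in/out side of node z. An odometer enumeration with
// incremental side sums keeps the full scan cheap.

static inline double node_term(double c, double tin, double tout, double w) {
  return (std::abs(c - tin) / 2.0 + std::abs(c - tout) / 2.0 +
          std::abs(tin - tout)) * w;
}

// [[Rcpp::export]]
List cpp_bf_edge_visits(IntegerVector lo, IntegerVector hi, IntegerVector sa,
                        IntegerVector sb, NumericVector cz, NumericVector wz) {
  int m = lo.size();
  int n = cz.size();
  std::vector<int> t(lo.begin(), lo.end());
  std::vector<double> side(2 * (size_t)n, 0.0);
  for (int e = 0; e < m; ++e) {
    side[(size_t)sa[e] - 1] += t[(size_t)e];
    side[(size_t)sb[e] - 1] += t[(size_t)e];
  }
  std::vector<double> nterm((size_t)n);
  double obj = 0;
  for (int z = 0; z < n; ++z) {
    nterm[(size_t)z] = node_term(cz[z], side[2 * (size_t)z], side[2 * (size_t)z + 1], wz[z]);
    obj += nterm[(size_t)z];
  }
  std::vector<int> best(t);
  double bobj = obj;

  auto bump = [&](int e, int delta) {
    t[(size_t)e] += delta;
    int za = (sa[e] - 1) / 2, zb = (sb[e] - 1) / 2;
    side[(size_t)sa[e] - 1] += delta;
    side[(size_t)sb[e] - 1] += delta;
    obj -= nterm[(size_t)za];
    nterm[(size_t)za] = node_term(cz[za], side[2 * (size_t)za], side[2 * (size_t)za + 1], wz[za]);
    obj += nterm[(size_t)za];
    if (zb != za) {
      obj -= nterm[(size_t)zb];
      nterm[(size_t)zb] = node_term(cz[zb], side[2 * (size_t)zb], side[2 * (size_t)zb + 1], wz[zb]);
      obj += nterm[(size_t)zb];
    }
  };

  while (true) {
    if (obj < bobj) { bobj = obj; best = t; }
    int e = 0;
    while (e < m && t[(size_t)e] == hi[e]) {
      bump(e, lo[e] - hi[e]);
      ++e;
    }
    if (e == m) break;
    bump(e, 1);
  }
  return List::create(_["t"] = wrap(best), _["objective"] = bobj);
}
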