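#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact minimal-cost row-monotone path ("geodesic") through a cost image.
//
// cost: nrow x ncol matrix, cost[r, c] = price of visiting column c in row r
//       (callers pass W_max - W so that large weights attract the path).
// lambda: per-column deviation penalty; dmax: hard step bound between rows.
// The path is closed across the row wrap by an extra lambda*|c_last - c_first|
// term (no step bound on the wrap).  Solved exactly by conditioning the DP on
// the start column; ties broken toward smaller column indices at every level,
// so the result is deterministic.
// [[Rcpp::export]]
List cpp_trace_geodesic(NumericMatrix cost, double lambda, int dmax) {
  const int R = cost.nrow(), C = cost.ncol();
  if (R < 2) stop("geodesic tracing needs at least 2 rows");
  if (C < 1) stop("empty cost image");
  if (dmax < 0) stop("d_max must be >= 0");
  const double INF = std::numeric_limits<double>::infinity();

  // Phase 1: propagate all start columns at once. D[s*C + c] = best cost of a
  // path starting in column s (row 0) and currently in column c.
  std::vector<double> D((size_t)C * C, INF), Dn((size_t)C * C);
  for (int s = 0; s < C; ++s) D[(size_t)s * C + s] = cost(0, s);
  for (int r = 1; r < R; ++r) {
    for (int s = 0; s < C; ++s) {
      const double* Ds = &D[(size_t)s * C];
      double* Dns = &Dn[(size_t)s * C];
      for (int c = 0; c < C; ++c) {
        double best = INF;
        int plo = std::max(0, c - dmax), phi = std::min(C - 1, c + dmax);
        for (int p = plo; p <= phi; ++p) {
          double v = Ds[p] + lambda * std::abs(c - p);
          if (v < best) best = v;
        }
        Dns[c] = best + cost(r, c);
      }
    }
    std::swap(D, Dn);
  }
  double bestCost = INF; int bestS = -1, bestE = -1;
  for (int s = 0; s < C; ++s)
    for (int e = 0; e < C; ++e) {
      double v = D[(size_t)s * C + e] + lambda * std::abs(e - s);
      if (v < bestCost) { bestCost = v; bestS = s; bestE = e; }
    }

  // Phase 2: rebuild the DP for the winning start column, keeping parents.
  std::vector<double> f(C, INF), fn(C);
  IntegerMatrix parent(R, C);
  f[bestS] = cost(0, bestS);
  for (int r = 1; r < R; ++r) {
    for (int c = 0; c < C; ++c) {
      double best = INF; int barg = -1;
      int plo = std::max(0, c - dmax), phi = std::min(C - 1, c + dmax);
      for (int p = plo; p <= phi; ++p) {
        double v = f[p] + lambda * std::abs(c - p);
        if (v < best) { best = v; barg = p; }
      }
      fn[c] = best + cost(r, c);
      parent(r, c) = barg;
    }
    std::swap(f, fn);
  }
  IntegerVector path(R);
  int c = bestE;
  for (int r = R - 1; r >= 1; --r) { path[r] = c + 1; c = parent(r, c); }
  path[0] = c + 1;  // equals bestS by construction
  return List::create(_["columns"] = path, _["cost"] = bestCost);
}

// Connected-component labeling of a binary mask, 8-connectivity in 2D or
// 26-connectivity in 3D (EBImage::bwlabel is 4-connected, which does not
// match the conventions used here).  dims has length 2 or 3.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  const int nd = dims.size();
  if (nd != 2 && nd != 3) stop("mask must be 2D or 3D");
  const int nx = dims[0], ny = dims[1], nz = (nd == 3) ? dims[2] : 1;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++cur;
    lab[i] = cur;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int x = v % nx, y = (v / nx) % ny, z = v / ((R_xlen_t)nx * ny);
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz; if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy; if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            int xx = x + dx; if (xx < 0 || xx >= nx) continue;
            if (!dx && !dy && !dz) continue;
            R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            if (mask[w] && !lab[w]) { lab[w] = cur; stack.push_back(w); }
          }
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
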