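#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Per-pixel GLCM contrast and energy over a sliding square window.
// q: 0-based quantized levels (0..l-1); pairs are ordered, distinct pixels
// within Chebyshev distance <= d, both endpoints inside the window.
// [[Rcpp::export]]
List cpp_glcm_window(const IntegerMatrix& q, int l, int d, int win) {
  const int nr = q.nrow(), nc = q.ncol();
  const int hw = win / 2;
  NumericMatrix contrast(nr, nc), energy(nr, nc);
  std::vector<double> hist(l * l);

  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      const int r0 = std::max(0, r - hw), r1 = std::min(nr - 1, r + hw);
      const int c0 = std::max(0, c - hw), c1 = std::min(nc - 1, c + hw);
      std::fill(hist.begin(), hist.end(), 0.0);
      double tot = 0.0;
      for (int rr = r0; rr <= r1; ++rr) {
        for (int cc = c0; cc <= c1; ++cc) {
          const int a = q(rr, cc);
          for (int dr = -d; dr <= d; ++dr) {
            for (int dc = -d; dc <= d; ++dc) {
              if (dr == 0 && dc == 0) continue;
              const int r2 = rr + dr, c2 = cc + dc;
              if (r2 < r0 || r2 > r1 || c2 < c0 || c2 > c1) continue;
              hist[a * l + q(r2, c2)] += 1.0;
              tot += 1.0;
            }
          }
        }
      }
      double con = 0.0, ene = 0.0;
      if (tot > 0) {
        for (int i = 0; i < l; ++i)
          for (int j = 0; j < l; ++j) {
            const double p = hist[i * l + j] / tot;
            if (p > 0) {
              con += p * (i - j) * (i - j);
              ene += p * p;
            }
          }
      }
      contrast(r, c) = con;
      energy(r, c) = ene;
    }
  }
  return List::create(_["contrast"] = contrast, _["energy"] = energy);
}

// 8-connected component labelling, labels assigned in column-major
// discovery order starting at 1; background = 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int> > qu;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      lab(r, c) = ++next;
      qu.push(std::make_pair(r, c));
      while (!qu.empty()) {
        const int cr = qu.front().first, cc2 = qu.front().second;
        qu.pop();
        for (int dr = -1; dr <= 1; ++dr)
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            const int r2 = cr + dr, c2 = cc2 + dc;
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            if (mask(r2, c2) && !lab(r2, c2)) {
              lab(r2, c2) = next;
              qu.push(std::make_pair(r2, c2));
            }
          }
      }
    }
  }
  return lab;
}

// Geodesic distance inside `region` from `sources` on the 8-connected grid
// (step costs 1 / sqrt(2)), by iterated forward/backward chamfer sweeps.
// Pixels outside region (or unreachable) get NA.
// [[Rcpp::export]]
NumericMatrix cpp_geodesic(const LogicalMatrix& region,
                           const LogicalMatrix& sources) {
  const int nr = region.nrow(), nc = region.ncol();
  const double INF = R_PosInf, SQ2 = std::sqrt(2.0);
  NumericMatrix g(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      g(r, c) = (region(r, c) && sources(r, c)) ? 0.0 : INF;

  bool changed = true;
  int guard = 0;
  while (changed && ++guard <= nr * nc) {
    changed = false;
    // forward sweep
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        if (!region(r, c)) continue;
        double best = g(r, c);
        const int drs[4] = {-1, -1, -1, 0};
        const int dcs[4] = {-1, 0, 1, -1};
        for (int k = 0; k < 4; ++k) {
          const int r2 = r + drs[k], c2 = c + dcs[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (!region(r2, c2)) continue;
          const double cost = (drs[k] != 0 && dcs[k] != 0) ? SQ2 : 1.0;
          if (g(r2, c2) + cost < best) best = g(r2, c2) + cost;
        }
        if (best < g(r, c)) { g(r, c) = best; changed = true; }
      }
    // backward sweep
    for (int c = nc - 1; c >= 0; --c)
      for (int r = nr - 1; r >= 0; --r) {
        if (!region(r, c)) continue;
        double best = g(r, c);
        const int drs[4] = {1, 1, 1, 0};
        const int dcs[4] = {1, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          const int r2 = r + drs[k], c2 = c + dcs[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (!region(r2, c2)) continue;
          const double cost = (drs[k] != 0 && dcs[k] != 0) ? SQ2 : 1.0;
          if (g(r2, c2) + cost < best) best = g(r2, c2) + cost;
        }
        if (best < g(r, c)) { g(r, c) = best; changed = true; }
      }
  }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (!R_finite(g(r, c))) g(r, c) = NA_REAL;
  return g;
}
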