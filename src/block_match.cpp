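#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive-search block matching between two frames.
// For each macroblock of `prev` (tiled with the given stride), every
// integer displacement (dy, dx) with |dy|,|dx| <= radius whose target block
// lies fully inside `next` is scored (SAD or SSD); the minimum wins, ties
// broken by smaller displacement magnitude, then by dx, then dy.
// Returns a matrix with one row per block:
// [row0, col0, dy, dx, cost, clamped, valid] (row0/col0 1-based top-left).
// Blocks whose intensity variance falls below var_thresh are marked
// invalid (low texture carries no motion information).
// [[Rcpp::export(name = ".block_match_core")]]
NumericMatrix block_match_core(NumericMatrix prev, NumericMatrix next_,
                               int block, int radius, int stride,
                               bool use_ssd, double var_thresh) {
  const int nr = prev.nrow(), nc = prev.ncol();
  std::vector<int> r0s, c0s;
  for (int r = 0; r + block <= nr; r += stride) r0s.push_back(r);
  for (int c = 0; c + block <= nc; c += stride) c0s.push_back(c);
  const int nblocks = r0s.size() * c0s.size();
  NumericMatrix out(nblocks, 7);
  int bi = 0;
  const double n_px = (double)block * block;

  for (size_t ri = 0; ri < r0s.size(); ++ri) {
    for (size_t ci = 0; ci < c0s.size(); ++ci, ++bi) {
      const int r0 = r0s[ri], c0 = c0s[ci];

      // texture check on the source block
      double s = 0.0, s2 = 0.0;
      for (int c = 0; c < block; ++c)
        for (int r = 0; r < block; ++r) {
          double v = prev(r0 + r, c0 + c);
          s += v; s2 += v * v;
        }
      double var = s2 / n_px - (s / n_px) * (s / n_px);
      bool valid = var >= var_thresh;

      double best = R_PosInf;
      int bdy = 0, bdx = 0;
      bool found = false;
      for (int dy = -radius; dy <= radius; ++dy) {
        const int tr = r0 + dy;
        if (tr < 0 || tr + block > nr) continue;
        for (int dx = -radius; dx <= radius; ++dx) {
          const int tc = c0 + dx;
          if (tc < 0 || tc + block > nc) continue;
          double cost = 0.0;
          for (int c = 0; c < block; ++c)
            for (int r = 0; r < block; ++r) {
              double d = prev(r0 + r, c0 + c) - next_(tr + r, tc + c);
              cost += use_ssd ? d * d : std::fabs(d);
            }
          bool better = false;
          if (!found || cost < best) better = true;
          else if (cost == best) {
            int m_new = dx * dx + dy * dy, m_old = bdx * bdx + bdy * bdy;
            if (m_new < m_old) better = true;
            else if (m_new == m_old &&
                     (dx < bdx || (dx == bdx && dy < bdy))) better = true;
          }
          if (better) { best = cost; bdy = dy; bdx = dx; found = true; }
        }
      }
      bool clamped = (std::abs(bdy) == radius || std::abs(bdx) == radius);
      out(bi, 0) = r0 + 1; out(bi, 1) = c0 + 1;
      out(bi, 2) = bdy;    out(bi, 3) = bdx;
      out(bi, 4) = best;
      out(bi, 5) = clamped ? 1.0 : 0.0;
      out(bi, 6) = valid ? 1.0 : 0.0;
    }
  }
  return out;
}
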