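#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// 8-connected component labeling of a binary grid.
// fg: integer matrix with 1 = foreground, 0 = background, NA = nodata.
// Nodata cells are non-foreground and non-connecting. Labels are assigned
// in row-major discovery order (row 1 scanned left to right first), so
// the labeling is deterministic.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(IntegerMatrix fg) {
  const int nr = fg.nrow(), nc = fg.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  stack.reserve(256);
  int next = 0;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (fg(r, c) == NA_INTEGER || fg(r, c) != 1 || lab(r, c) != 0)
        continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r * nc + c);
      while (!stack.empty()) {
        int cur = stack.back();
        stack.pop_back();
        int cr = cur / nc, cc = cur % nc;
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            int rr = cr + dr, cs = cc + dc;
            if (rr < 0 || rr >= nr || cs < 0 || cs >= nc) continue;
            if (fg(rr, cs) == NA_INTEGER || fg(rr, cs) != 1) continue;
            if (lab(rr, cs) != 0) continue;
            lab(rr, cs) = next;
            stack.push_back(rr * nc + cs);
          }
        }
      }
    }
  }
  return lab;
}

// Per-patch Euclidean nearest-neighbour distance (cell centre to cell
// centre), in the units of cellSize. For each patch the minimum over all
// other patches of the minimum pairwise cell distance. Only boundary
// cells (cells with at least one 8-neighbour, or grid edge, that is not
// the same patch) need be considered: the nearest cells of two distinct
// patches are always boundary cells. Returns NA when only one patch.
// [[Rcpp::export]]
NumericVector cpp_patch_enn(IntegerMatrix lab, int npatch, double cellSize) {
  const int nr = lab.nrow(), nc = lab.ncol();
  NumericVector enn(npatch, NA_REAL);
  if (npatch < 2) return enn;

  std::vector<int> br, bc, bl;  // boundary cell rows, cols, labels
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      int l = lab(r, c);
      if (l <= 0) continue;
      bool boundary = false;
      for (int dr = -1; dr <= 1 && !boundary; ++dr) {
        for (int dc = -1; dc <= 1 && !boundary; ++dc) {
          if (dr == 0 && dc == 0) continue;
          int rr = r + dr, cs = c + dc;
          if (rr < 0 || rr >= nr || cs < 0 || cs >= nc) { boundary = true; break; }
          if (lab(rr, cs) != l) boundary = true;
        }
      }
      if (boundary) { br.push_back(r); bc.push_back(c); bl.push_back(l); }
    }
  }

  std::vector<double> best(npatch + 1,
                           std::numeric_limits<double>::infinity());
  const int nb = (int) br.size();
  for (int i = 0; i < nb; ++i) {
    const int li = bl[i];
    for (int j = i + 1; j < nb; ++j) {
      if (bl[j] == li) continue;
      const double dr = (double)(br[i] - br[j]);
      const double dc = (double)(bc[i] - bc[j]);
      const double d2 = dr * dr + dc * dc;
      if (d2 < best[li]) best[li] = d2;
      if (d2 < best[bl[j]]) best[bl[j]] = d2;
    }
  }
  for (int p = 1; p <= npatch; ++p)
    if (std::isfinite(best[p]))
      enn[p - 1] = std::sqrt(best[p]) * cellSize;
  return enn;
}
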