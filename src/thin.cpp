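#include <Rcpp.h>
using namespace Rcpp;

// Zhang-Suen thinning. Input: integer 0/1 matrix. Output: 0/1 matrix of the
// same shape whose foreground is a one-pixel-wide, 8-connected skeleton and a
// subset of the input foreground.
//
// Neighbour layout (P2..P9 clockwise from north), image stored column-major:
//   P9 P2 P3
//   P8 P1 P4
//   P7 P6 P5

static inline int px(const IntegerMatrix &m, int r, int c) {
  if (r < 0 || c < 0 || r >= m.nrow() || c >= m.ncol()) return 0;
  return m(r, c);
}

// [[Rcpp::export(name = ".zs_thin")]]
IntegerMatrix zs_thin(IntegerMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix m = clone(img);
  std::vector<std::pair<int,int> > del;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      del.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!m(r, c)) continue;
          int p2 = px(m, r - 1, c),     p3 = px(m, r - 1, c + 1);
          int p4 = px(m, r,     c + 1), p5 = px(m, r + 1, c + 1);
          int p6 = px(m, r + 1, c),     p7 = px(m, r + 1, c - 1);
          int p8 = px(m, r,     c - 1), p9 = px(m, r - 1, c - 1);
          int b = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (b < 2 || b > 6) continue;
          int a = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (a != 1) continue;
          if (sub == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          del.push_back(std::make_pair(r, c));
        }
      }
      if (!del.empty()) changed = true;
      for (size_t i = 0; i < del.size(); ++i) m(del[i].first, del[i].second) = 0;
    }
  }
  return m;
}

// Minimality cleanup: sequentially delete pixels whose foreground neighbours
// remain mutually 8-connected without the pixel (redundant staircase/corner
// pixels).  Leaves endpoints (single neighbour) untouched.  After this pass a
// path pixel has exactly two mutually non-adjacent neighbours, so neighbour
// counting classifies nodes correctly.
// [[Rcpp::export(name = ".thin_clean")]]
IntegerMatrix thin_clean(IntegerMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix m = clone(img);
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  bool changed = true;
  while (changed) {
    changed = false;
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        if (!m(r, c)) continue;
        int nb_r[8], nb_c[8], n = 0;
        for (int k = 0; k < 8; ++k) {
          int rr = r + dr[k], cc = c + dc[k];
          if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
          if (m(rr, cc)) { nb_r[n] = rr; nb_c[n] = cc; ++n; }
        }
        if (n < 2) continue;
        // are the neighbours one component under their mutual 8-adjacency?
        int comp[8];
        for (int i = 0; i < n; ++i) comp[i] = i;
        bool merged = true;
        while (merged) {
          merged = false;
          for (int i = 0; i < n; ++i)
            for (int j = i + 1; j < n; ++j) {
              if (comp[i] == comp[j]) continue;
              if (std::abs(nb_r[i] - nb_r[j]) <= 1 &&
                  std::abs(nb_c[i] - nb_c[j]) <= 1) {
                int a = comp[i], b = comp[j];
                for (int k = 0; k < n; ++k) if (comp[k] == b) comp[k] = a;
                merged = true;
              }
            }
        }
        bool one = true;
        for (int i = 1; i < n; ++i) if (comp[i] != comp[0]) one = false;
        if (one) { m(r, c) = 0; changed = true; }
      }
    }
  }
  return m;
}
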