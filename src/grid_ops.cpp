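#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Grid conventions used throughout: class codes are NA (nodata), 0
// (non-vegetated background) or 1..m (height classes). Labels are 0 for
// background/nodata, 1..n_patch for patches, assigned in scan order.

// [[Rcpp::export]]
IntegerMatrix cc_label(IntegerMatrix cls, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = cls.nrow(), nc = cls.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  const int dr4[] = {-1, 1, 0, 0}, dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1}, dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = (connectivity == 4) ? dr4 : dr8;
  const int *dc = (connectivity == 4) ? dc4 : dc8;
  const int ndir = connectivity;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int v = cls(r, c);
      if (v == NA_INTEGER || v <= 0 || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int d = 0; d < ndir; ++d) {
          int r2 = rr + dr[d], c2 = cc + dc[d];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (lab(r2, c2) != 0) continue;
          int v2 = cls(r2, c2);
          if (v2 == NA_INTEGER || v2 != v) continue;
          lab(r2, c2) = next;
          stack.push_back(r2 + c2 * nr);
        }
      }
    }
  }
  return lab;
}

// Per-patch geometry and boundary contrast. For each labelled patch:
//  - ncell: member cell count
//  - perim_faces: faces to anything that is not the same patch, including
//    grid boundary and nodata (true geometric perimeter, FRAGSTATS style)
//  - edge_faces: faces to a *different class* cell (background included),
//    excluding nodata and grid boundary
//  - edge_depth: sum of contrast weights over those same faces.
// contrast is (m+1)x(m+1) indexed by class code 0..m.
// [[Rcpp::export]]
List patch_stats(IntegerMatrix cls, IntegerMatrix lab, NumericMatrix contrast,
                 int n_patch) {
  const int nr = cls.nrow(), nc = cls.ncol();
  IntegerVector ncell(n_patch), perim(n_patch), efaces(n_patch);
  NumericVector edepth(n_patch);
  IntegerVector pclass(n_patch, NA_INTEGER);
  const int dr[] = {-1, 1, 0, 0}, dc[] = {0, 0, -1, 1};
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int L = lab(r, c);
      if (L == 0) continue;
      int v = cls(r, c);
      ncell[L - 1]++;
      pclass[L - 1] = v;
      for (int d = 0; d < 4; ++d) {
        int r2 = r + dr[d], c2 = c + dc[d];
        bool off = (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc);
        if (off) { perim[L - 1]++; continue; }
        int v2 = cls(r2, c2);
        if (v2 == NA_INTEGER) { perim[L - 1]++; continue; }
        if (lab(r2, c2) != L) perim[L - 1]++;
        if (v2 != v) {
          if (v >= contrast.nrow() || v2 >= contrast.ncol())
            stop("class code outside contrast matrix");
          efaces[L - 1]++;
          edepth[L - 1] += contrast(v, v2);
        }
      }
    }
  }
  return List::create(_["class"] = pclass, _["ncell"] = ncell,
                      _["perim_faces"] = perim, _["edge_faces"] = efaces,
                      _["edge_depth_sum"] = edepth);
}

// Counts of 4-adjacent heterogeneous cell pairs by unordered class pair
// (codes 0..m). Nodata and grid boundary contribute nothing. Each shared
// face is counted once.
// [[Rcpp::export]]
IntegerMatrix edge_face_counts(IntegerMatrix cls, int n_class) {
  const int nr = cls.nrow(), nc = cls.ncol();
  IntegerMatrix out(n_class + 1, n_class + 1);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int v = cls(r, c);
      if (v == NA_INTEGER) continue;
      if (r + 1 < nr) {
        int v2 = cls(r + 1, c);
        if (v2 != NA_INTEGER && v2 != v) {
          int a = std::min(v, v2), b = std::max(v, v2);
          out(a, b)++;
        }
      }
      if (c + 1 < nc) {
        int v2 = cls(r, c + 1);
        if (v2 != NA_INTEGER && v2 != v) {
          int a = std::min(v, v2), b = std::max(v, v2);
          out(a, b)++;
        }
      }
    }
  }
  return out;
}

// Pooled grey-level co-occurrence counts over a set of pixel offsets.
// g holds levels 0..levels-1 or NA; pairs touching NA or leaving the grid
// are skipped. symmetric = count each pair in both orders.
// [[Rcpp::export]]
NumericMatrix glcm_counts(IntegerMatrix g, IntegerMatrix offsets, int levels,
                          bool symmetric) {
  const int nr = g.nrow(), nc = g.ncol(), no = offsets.nrow();
  NumericMatrix out(levels, levels);
  for (int o = 0; o < no; ++o) {
    int dr = offsets(o, 0), dc = offsets(o, 1);
    for (int c = 0; c < nc; ++c) {
      int c2 = c + dc;
      if (c2 < 0 || c2 >= nc) continue;
      for (int r = 0; r < nr; ++r) {
        int r2 = r + dr;
        if (r2 < 0 || r2 >= nr) continue;
        int a = g(r, c), b = g(r2, c2);
        if (a == NA_INTEGER || b == NA_INTEGER) continue;
        out(a, b) += 1.0;
        if (symmetric) out(b, a) += 1.0;
      }
    }
  }
  return out;
}
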