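#include <Rcpp.h>
using namespace Rcpp;

// Two-pass connected-component labelling with 8-connectivity (ImageJ
// "Analyze Particles" convention). Input: logical/integer matrix, non-zero =
// foreground. Output: integer matrix, components numbered 1..n in raster
// order of first encounter.

static int find_root(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void unite(std::vector<int>& parent, int a, int b) {
  int ra = find_root(parent, a), rb = find_root(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// [[Rcpp::export]]
IntegerMatrix label_components8(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.push_back(0); // dummy so labels are 1-based

  int next = 1;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      // neighbours already visited in column-major order:
      // (r-1,c), (r-1,c-1), (r,c-1), (r+1,c-1)
      int best = 0;
      int nb[4][2] = {{r - 1, c}, {r - 1, c - 1}, {r, c - 1}, {r + 1, c - 1}};
      for (int k = 0; k < 4; ++k) {
        int rr = nb[k][0], cc = nb[k][1];
        if (rr < 0 || rr >= nr || cc < 0) continue;
        int l = lab(rr, cc);
        if (l > 0) {
          if (best == 0) best = l;
          else if (l != best) { unite(parent, best, l); best = std::min(best, l); }
        }
      }
      if (best == 0) {
        parent.push_back(next);
        lab(r, c) = next++;
      } else {
        lab(r, c) = best;
      }
    }
  }

  // flatten and renumber 1..n in order of first appearance
  std::vector<int> newlab(next, 0);
  int n = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      int root = find_root(parent, l);
      if (newlab[root] == 0) newlab[root] = ++n;
      lab(r, c) = newlab[root];
    }
  return lab;
}
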