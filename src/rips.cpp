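#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Vietoris-Rips persistent homology of a 3D point cloud, dimensions 0 and 1.
//
// Filtration convention: an edge enters at the Euclidean distance between its
// endpoints; a triangle enters at the length of its longest edge.
//
// H0: union-find over edges sorted by length. Finite H0 deaths are exactly the
// single-linkage merge heights (MST edge lengths); one essential class remains.
//
// H1: standard persistence reduction of the triangle boundary matrix over
// GF(2). Columns are triangles in filtration order; rows are edges in
// filtration order; the pivot of a reduced non-zero column pairs its edge
// (birth) with the triangle (death). Zero-persistence pairs are dropped.
// Edges that merge components (negative edges in H0) never give birth to a
// loop and are excluded as pivots by construction of the reduction order; the
// reduction handles this implicitly because their columns are cleared first
// via the pairing with connected components -- here we simply run the textbook
// dim-1 reduction, which yields the correct pairs because boundaries of
// triangles only involve edges.

namespace {

struct UnionFind {
  std::vector<int> parent;
  explicit UnionFind(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  bool unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return false;
    parent[a] = b;
    return true;
  }
};

struct EdgeRec {
  double d;
  int i, j;
};

struct TriRec {
  double val;
  int e1, e2, e3;  // edge ranks, sorted ascending
};

// symmetric difference of two ascending int vectors into out
void sym_diff(const std::vector<int>& a, const std::vector<int>& b,
              std::vector<int>& out) {
  out.clear();
  std::set_symmetric_difference(a.begin(), a.end(), b.begin(), b.end(),
                                std::back_inserter(out));
}

}  // namespace

// [[Rcpp::export]]
List rips_pairs_cpp(NumericMatrix pts, double threshold, bool compute_h1) {
  const int n = pts.nrow();
  if (n < 2) stop("need at least 2 points");
  if (n > 3000) stop("point cloud too large for dense Rips computation");

  // pairwise edges within threshold
  std::vector<EdgeRec> edges;
  edges.reserve(static_cast<size_t>(n) * (n - 1) / 2);
  for (int i = 0; i < n; ++i) {
    const double xi = pts(i, 0), yi = pts(i, 1), zi = pts(i, 2);
    for (int j = i + 1; j < n; ++j) {
      const double dx = pts(j, 0) - xi, dy = pts(j, 1) - yi, dz = pts(j, 2) - zi;
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d <= threshold) edges.push_back({d, i, j});
    }
  }
  std::sort(edges.begin(), edges.end(), [](const EdgeRec& a, const EdgeRec& b) {
    if (a.d != b.d) return a.d < b.d;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  });
  const int m = static_cast<int>(edges.size());

  // H0 via union-find in edge order
  UnionFind uf(n);
  std::vector<double> h0_deaths;
  h0_deaths.reserve(n - 1);
  for (int e = 0; e < m; ++e) {
    if (uf.unite(edges[e].i, edges[e].j)) h0_deaths.push_back(edges[e].d);
  }
  int n_components = n - static_cast<int>(h0_deaths.size());  // essential H0

  std::vector<double> h1_births, h1_deaths;
  int h1_essential = 0;

  if (compute_h1 && m > 0) {
    // edge rank lookup
    std::vector<int> rank(static_cast<size_t>(n) * n, -1);
    std::vector<double> edge_len(m);
    for (int e = 0; e < m; ++e) {
      rank[static_cast<size_t>(edges[e].i) * n + edges[e].j] = e;
      edge_len[e] = edges[e].d;
    }

    // enumerate triangles with all edges within threshold
    std::vector<TriRec> tris;
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        const int rij = rank[static_cast<size_t>(i) * n + j];
        if (rij < 0) continue;
        for (int k = j + 1; k < n; ++k) {
          const int rik = rank[static_cast<size_t>(i) * n + k];
          if (rik < 0) continue;
          const int rjk = rank[static_cast<size_t>(j) * n + k];
          if (rjk < 0) continue;
          int a = rij, b = rik, c = rjk;
          // sort ranks ascending; filtration value = longest edge
          if (a > b) std::swap(a, b);
          if (b > c) std::swap(b, c);
          if (a > b) std::swap(a, b);
          tris.push_back({edge_len[c], a, b, c});
        }
      }
    }
    // filtration order: by value, ties by max edge rank then lexicographic
    std::sort(tris.begin(), tris.end(), [](const TriRec& a, const TriRec& b) {
      if (a.val != b.val) return a.val < b.val;
      if (a.e3 != b.e3) return a.e3 < b.e3;
      if (a.e2 != b.e2) return a.e2 < b.e2;
      return a.e1 < b.e1;
    });

    std::vector<int> pivot_owner(m, -1);
    std::vector<std::vector<int> > cols;
    std::vector<int> work, tmp;
    const size_t nt = tris.size();
    size_t checked = 0;
    for (size_t t = 0; t < nt; ++t) {
      if (++checked % 100000 == 0) Rcpp::checkUserInterrupt();
      work.clear();
      work.push_back(tris[t].e1);
      work.push_back(tris[t].e2);
      work.push_back(tris[t].e3);
      while (!work.empty()) {
        const int piv = work.back();
        const int owner = pivot_owner[piv];
        if (owner < 0) break;
        sym_diff(work, cols[owner], tmp);
        work.swap(tmp);
      }
      if (!work.empty()) {
        const int piv = work.back();
        pivot_owner[piv] = static_cast<int>(cols.size());
        cols.push_back(work);
        const double birth = edge_len[piv];
        if (tris[t].val > birth) {
          h1_births.push_back(birth);
          h1_deaths.push_back(tris[t].val);
        }
      }
    }

    // essential H1 classes: positive edges (non-merging) that never became a
    // pivot of a reduced triangle column
    UnionFind uf2(n);
    for (int e = 0; e < m; ++e) {
      if (!uf2.unite(edges[e].i, edges[e].j) && pivot_owner[e] < 0) {
        ++h1_essential;
      }
    }
  }

  return List::create(
      _["h0_deaths"] = wrap(h0_deaths),
      _["n_h0_essential"] = n_components,
      _["h1_births"] = wrap(h1_births),
      _["h1_deaths"] = wrap(h1_deaths),
      _["n_h1_essential"] = h1_essential,
      _["n_edges"] = m);
}
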