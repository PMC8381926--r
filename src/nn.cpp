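#include <Rcpp.h>
#include <algorithm>
#include <vector>

// 3-d kd-tree over an n x 3 point matrix (row-major access into R's
// column-major storage via stride n). Median-split, implicit balanced layout.
// Ties in distance are broken towards the smaller reference row index so that
// matching is deterministic.

namespace {

struct KDTree {
  const double *pts;            // column-major, n rows
  int n;
  std::vector<int> idx;

  double coord(int i, int ax) const { return pts[i + (std::size_t)n * ax]; }

  void build(int lo, int hi, int depth) {
    if (hi - lo <= 1) return;
    int mid = (lo + hi) / 2;
    int ax = depth % 3;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [&](int a, int b) {
                       double ca = coord(a, ax), cb = coord(b, ax);
                       if (ca != cb) return ca < cb;
                       return a < b;
                     });
    build(lo, mid, depth + 1);
    build(mid + 1, hi, depth + 1);
  }

  void query(int lo, int hi, int depth, const double *q, int &best,
             double &bestd) const {
    if (hi <= lo) return;
    int mid = (lo + hi) / 2;
    int p = idx[mid];
    double dx = coord(p, 0) - q[0];
    double dy = coord(p, 1) - q[1];
    double dz = coord(p, 2) - q[2];
    double d = dx * dx + dy * dy + dz * dz;
    if (d < bestd || (d == bestd && p < best)) {
      bestd = d;
      best = p;
    }
    int ax = depth % 3;
    double diff = q[ax] - coord(p, ax);
    int nlo, nhi, flo, fhi;
    if (diff < 0) {
      nlo = lo; nhi = mid; flo = mid + 1; fhi = hi;
    } else {
      nlo = mid + 1; nhi = hi; flo = lo; fhi = mid;
    }
    query(nlo, nhi, depth + 1, q, best, bestd);
    if (diff * diff <= bestd) query(flo, fhi, depth + 1, q, best, bestd);
  }
};

}  // namespace

// [[Rcpp::export(name = ".nn_index")]]
Rcpp::List nn_index(Rcpp::NumericMatrix ref, Rcpp::NumericMatrix query) {
  if (ref.ncol() != 3 || query.ncol() != 3)
    Rcpp::stop("point matrices must have 3 columns");
  int n = ref.nrow(), m = query.nrow();
  if (n < 1) Rcpp::stop("reference set is empty");
  KDTree tree;
  tree.pts = ref.begin();
  tree.n = n;
  tree.idx.resize(n);
  for (int i = 0; i < n; ++i) tree.idx[i] = i;
  tree.build(0, n, 0);

  Rcpp::IntegerVector out_idx(m);
  Rcpp::NumericVector out_dist(m);
  double q[3];
  for (int j = 0; j < m; ++j) {
    q[0] = query(j, 0);
    q[1] = query(j, 1);
    q[2] = query(j, 2);
    int best = -1;
    double bestd = R_PosInf;
    tree.query(0, n, 0, q, best, bestd);
    out_idx[j] = best + 1;  // 1-based for R
    out_dist[j] = std::sqrt(bestd);
  }
  return Rcpp::List::create(Rcpp::Named("index") = out_idx,
                            Rcpp::Named("dist") = out_dist);
}
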