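// Weighted graph-metric kernels used by the sparsity sweep.
// Conventions: edge length for shortest paths is 1/w (mode 1) or -log(w)
// (mode 2); clustering uses geometric-mean triangle intensities on weights
// normalised by the graph maximum, with a binary-degree denominator by
// default (strength denominator available as mode 2).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat fw_distances(const arma::mat& W, const int length_mode) {
  const arma::uword n = W.n_rows;
  arma::mat D(n, n);
  D.fill(arma::datum::inf);
  D.diag().zeros();
  for (arma::uword i = 0; i < n; ++i)
    for (arma::uword j = 0; j < n; ++j)
      if (i != j && W(i, j) > 0.0)
        D(i, j) = (length_mode == 1) ? 1.0 / W(i, j) : -std::log(W(i, j));
  for (arma::uword k = 0; k < n; ++k)
    for (arma::uword i = 0; i < n; ++i) {
      const double dik = D(i, k);
      if (!std::isfinite(dik)) continue;
      for (arma::uword j = 0; j < n; ++j) {
        const double alt = dik + D(k, j);
        if (alt < D(i, j)) D(i, j) = alt;
      }
    }
  return D;
}

// [[Rcpp::export]]
arma::mat fw_dist_cpp(const arma::mat& W, const int length_mode) {
  return fw_distances(W, length_mode);
}

static arma::vec efficiency_from_dist(const arma::mat& D) {
  const arma::uword n = D.n_rows;
  arma::vec E(n, arma::fill::zeros);
  if (n < 2) return E;
  for (arma::uword i = 0; i < n; ++i) {
    double acc = 0.0;
    for (arma::uword j = 0; j < n; ++j) {
      if (i == j) continue;
      const double d = D(i, j);
      if (std::isfinite(d) && d > 0.0) acc += 1.0 / d;
    }
    E(i) = acc / static_cast<double>(n - 1);
  }
  return E;
}

static arma::vec clustering_vec(const arma::mat& W, const bool norm_max,
                                const int denom_mode) {
  const arma::uword n = W.n_rows;
  arma::vec C(n, arma::fill::zeros);
  const double wmax = W.max();
  if (wmax <= 0.0) return C;
  arma::mat Wh = norm_max ? arma::mat(W / wmax) : W;
  Wh.transform([](double v) { return v > 0.0 ? std::cbrt(v) : 0.0; });
  const arma::mat cube = Wh * Wh * Wh;
  for (arma::uword i = 0; i < n; ++i) {
    const double t_i = cube(i, i) / 2.0;
    double denom;
    if (denom_mode == 1) {
      const double deg = static_cast<double>(
          arma::accu(W.row(i) > 0.0));
      denom = deg * (deg - 1.0);
    } else {
      const double k_i = arma::accu(W.row(i));
      denom = k_i * (k_i - 1.0);
    }
    C(i) = (denom > 0.0) ? 2.0 * t_i / denom : 0.0;
  }
  return C;
}

// [[Rcpp::export]]
List nodal_metrics_cpp(const arma::mat& W, const int length_mode,
                       const bool norm_max, const int denom_mode) {
  const arma::vec strength = arma::sum(W, 1);
  const arma::mat D = fw_distances(W, length_mode);
  const arma::vec eff = efficiency_from_dist(D);
  const arma::vec clust = clustering_vec(W, norm_max, denom_mode);
  return List::create(_["strength"] = strength, _["efficiency"] = eff,
                      _["clustering"] = clust);
}

struct Edge {
  double w;
  int i;  // 0-based, i < j
  int j;
};

// Positive upper-triangle edges, descending weight, ties in (i, j) order.
static std::vector<Edge> sorted_edges(const arma::mat& Z) {
  const int n = static_cast<int>(Z.n_rows);
  std::vector<Edge> edges;
  edges.reserve(static_cast<size_t>(n) * (n - 1) / 2);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (Z(i, j) > 0.0) edges.push_back({Z(i, j), i, j});
  std::stable_sort(edges.begin(), edges.end(),
                   [](const Edge& a, const Edge& b) { return a.w > b.w; });
  return edges;
}

// Metrics at every level of an edge-count grid; levels must be
// non-decreasing so the graph can be grown incrementally.
// [[Rcpp::export]]
List metric_grid_cpp(const arma::mat& Z, const IntegerVector& counts,
                     const int length_mode, const bool norm_max,
                     const int denom_mode) {
  const int n = static_cast<int>(Z.n_rows);
  const int L = counts.size();
  const std::vector<Edge> edges = sorted_edges(Z);
  const int npos = static_cast<int>(edges.size());
  arma::mat strength(L, n), eff(L, n), clust(L, n);
  IntegerVector kept(L);
  arma::mat W(n, n, arma::fill::zeros);
  int placed = 0;
  for (int l = 0; l < L; ++l) {
    int target = std::min(counts[l], npos);
    if (target < placed) stop("edge-count grid must be non-decreasing");
    for (; placed < target; ++placed) {
      const Edge& e = edges[placed];
      W(e.i, e.j) = e.w;
      W(e.j, e.i) = e.w;
    }
    kept[l] = placed;
    strength.row(l) = arma::sum(W, 1).t();
    eff.row(l) = efficiency_from_dist(fw_distances(W, length_mode)).t();
    clust.row(l) = clustering_vec(W, norm_max, denom_mode).t();
  }
  return List::create(_["strength"] = strength, _["efficiency"] = eff,
                      _["clustering"] = clust, _["n_edges_kept"] = kept);
}
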