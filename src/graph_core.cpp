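#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// All-pairs shortest path lengths by repeated Dijkstra on a dense
// connection-length matrix. len(i,j) is the length of the direct
// connection (Inf or non-finite = absent). Dense O(n^3); the graphs
// here have at most a few dozen nodes.
// [[Rcpp::export]]
NumericMatrix cpp_dijkstra_all(NumericMatrix len) {
  const int n = len.nrow();
  NumericMatrix d(n, n);
  std::vector<double> dist(n);
  std::vector<char> done(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    std::fill(done.begin(), done.end(), 0);
    dist[s] = 0.0;
    for (int it = 0; it < n; ++it) {
      int u = -1;
      double best = R_PosInf;
      for (int v = 0; v < n; ++v)
        if (!done[v] && dist[v] < best) { best = dist[v]; u = v; }
      if (u < 0) break;
      done[u] = 1;
      for (int v = 0; v < n; ++v) {
        if (done[v]) continue;
        double l = len(u, v);
        if (R_FINITE(l) && dist[u] + l < dist[v]) dist[v] = dist[u] + l;
      }
    }
    for (int v = 0; v < n; ++v) d(s, v) = dist[v];
  }
  return d;
}

// One Louvain run (greedy modularity optimisation with graph
// aggregation) on a symmetric weighted adjacency matrix with zero
// diagonal. `order` is a 1-based node visiting order for the first
// level; deeper levels visit aggregated nodes in index order, so all
// randomisation comes from `order`. Returns 1-based community labels
// for the original nodes. Modularity convention:
//   Q = (1/m2) * sum_ij [ W_ij - gamma * k_i k_j / m2 ] delta(c_i, c_j),
// with k_i = row strength and m2 = sum(W) (twice the total edge weight).
// [[Rcpp::export]]
IntegerVector cpp_louvain(NumericMatrix W, double gamma, IntegerVector order) {
  const int n0 = W.nrow();
  std::vector<std::vector<double> > B(n0, std::vector<double>(n0));
  double m2 = 0.0;
  for (int i = 0; i < n0; ++i)
    for (int j = 0; j < n0; ++j) { B[i][j] = W(i, j); m2 += W(i, j); }
  if (m2 <= 0) stop("graph has no positive weight");

  // membership of each original node through the levels
  std::vector<int> node2comm(n0);
  for (int i = 0; i < n0; ++i) node2comm[i] = i;

  std::vector<int> visit(n0);
  for (int i = 0; i < n0; ++i) visit[i] = order[i] - 1;

  int n = n0;
  bool improved_any_level = true;
  const double eps = 1e-12;

  while (improved_any_level) {
    // local-move phase on the current (possibly aggregated) graph
    std::vector<int> comm(n);
    for (int i = 0; i < n; ++i) comm[i] = i;
    std::vector<double> k(n, 0.0), tot(n, 0.0);
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < n; ++j) s += B[i][j];
      k[i] = s;
      tot[i] = s;
    }
    bool moved = true;
    bool any_move = false;
    while (moved) {
      moved = false;
      for (int vi = 0; vi < n; ++vi) {
        int i = visit[vi];
        int ci = comm[i];
        // weights from i to each community (self-loop excluded)
        std::vector<double> w2c(n, 0.0);
        for (int j = 0; j < n; ++j)
          if (j != i && B[i][j] != 0.0) w2c[comm[j]] += B[i][j];
        tot[ci] -= k[i];
        // gain of joining community c: w2c[c] - gamma * k_i * tot_c / m2
        int best_c = ci;
        double base = w2c[ci] - gamma * k[i] * tot[ci] / m2;
        double best_gain = base;
        for (int c = 0; c < n; ++c) {
          if (c == ci || (w2c[c] == 0.0 && tot[c] == 0.0)) continue;
          double g = w2c[c] - gamma * k[i] * tot[c] / m2;
          if (g > best_gain + eps) { best_gain = g; best_c = c; }
        }
        tot[best_c] += k[i];
        if (best_c != ci) { comm[i] = best_c; moved = true; any_move = true; }
      }
    }
    if (!any_move) break;

    // relabel communities 0..nc-1
    std::vector<int> relabel(n, -1);
    int nc = 0;
    for (int i = 0; i < n; ++i)
      if (relabel[comm[i]] < 0) relabel[comm[i]] = nc++;
    for (int i = 0; i < n; ++i) comm[i] = relabel[comm[i]];
    for (int i = 0; i < n0; ++i) node2comm[i] = comm[node2comm[i]];

    if (nc == n) break;

    // aggregation phase
    std::vector<std::vector<double> > Bn(nc, std::vector<double>(nc, 0.0));
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        Bn[comm[i]][comm[j]] += B[i][j];
    B.swap(Bn);
    n = nc;
    visit.resize(n);
    for (int i = 0; i < n; ++i) visit[i] = i;
    improved_any_level = true;
  }

  IntegerVector out(n0);
  // relabel 1..K in order of first appearance
  std::vector<int> relabel(n0, -1);
  int k2 = 0;
  for (int i = 0; i < n0; ++i) {
    if (relabel[node2comm[i]] < 0) relabel[node2comm[i]] = ++k2;
    out[i] = relabel[node2comm[i]];
  }
  return out;
}

// Maslov-Sneppen degree-preserving rewiring of a weighted undirected
// graph; weights travel with their edges, so the weight multiset is
// retained. `iter_per_edge` swap attempts are made per edge, following
// the usual connectivity-toolbox convention. Uses R's RNG, so results
// are reproducible under set.seed(). On complete graphs no legal swap
// exists and the graph is returned unchanged.
// [[Rcpp::export]]
NumericMatrix cpp_rewire(NumericMatrix W, int iter_per_edge) {
  const int n = W.nrow();
  NumericMatrix A = clone(W);
  std::vector<int> ei, ej;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (A(i, j) != 0.0) { ei.push_back(i); ej.push_back(j); }
  const int ne = (int)ei.size();
  if (ne < 2) return A;
  const long attempts = (long)iter_per_edge * ne;
  for (long t = 0; t < attempts; ++t) {
    int e1 = (int)(unif_rand() * ne);
    int e2 = (int)(unif_rand() * ne);
    if (e1 == e2) continue;
    int a = ei[e1], b = ej[e1], c = ei[e2], d = ej[e2];
    if (unif_rand() < 0.5) std::swap(c, d);
    if (a == c || a == d || b == c || b == d) continue;
    if (A(a, d) != 0.0 || A(c, b) != 0.0) continue;
    double w1 = A(a, b), w2 = A(c, d);
    A(a, b) = A(b, a) = 0.0;
    A(c, d) = A(d, c) = 0.0;
    A(a, d) = A(d, a) = w1;
    A(c, b) = A(b, c) = w2;
    ei[e1] = std::min(a, d); ej[e1] = std::max(a, d);
    ei[e2] = std::min(c, b); ej[e2] = std::max(c, b);
  }
  return A;
}

// Clustering (Onnela, weights rescaled by max) and characteristic path
// length (inverse-weight lengths, mean finite off-diagonal distance)
// of `n_null` Maslov-Sneppen rewired surrogates of W. Returns an
// n_null x 2 matrix (C_null, L_null). Doing the whole null loop in
// C++ keeps small-worldness cheap enough to run cohort-scale
// calibrations.
// [[Rcpp::export]]
NumericMatrix cpp_smallworld_nulls(NumericMatrix W, int n_null,
                                   int iter_per_edge) {
  const int n = W.nrow();
  NumericMatrix out(n_null, 2);
  std::vector<double> len(n * n), dist(n);
  std::vector<char> done(n);
  for (int t = 0; t < n_null; ++t) {
    NumericMatrix A = cpp_rewire(W, iter_per_edge);
    // Onnela clustering
    double mx = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) if (A(i, j) > mx) mx = A(i, j);
    double Csum = 0.0;
    if (mx > 0) {
      std::vector<double> Wh(n * n);
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j)
          Wh[i * n + j] = std::cbrt(A(i, j) / mx);
      for (int i = 0; i < n; ++i) {
        int k = 0;
        for (int j = 0; j < n; ++j) if (A(i, j) > 0) ++k;
        if (k < 2) continue;
        double cyc = 0.0;
        for (int j = 0; j < n; ++j) {
          if (Wh[i * n + j] == 0.0) continue;
          for (int h = 0; h < n; ++h)
            cyc += Wh[i * n + j] * Wh[j * n + h] * Wh[h * n + i];
        }
        Csum += cyc / (double)(k * (k - 1));
      }
    }
    out(t, 0) = Csum / n;
    // CPL via Dijkstra on 1/w lengths
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        len[i * n + j] = (A(i, j) > 0) ? 1.0 / A(i, j) : R_PosInf;
    double dsum = 0.0;
    long dcount = 0;
    for (int s = 0; s < n; ++s) {
      std::fill(dist.begin(), dist.end(), R_PosInf);
      std::fill(done.begin(), done.end(), 0);
      dist[s] = 0.0;
      for (int it = 0; it < n; ++it) {
        int u = -1; double best = R_PosInf;
        for (int v = 0; v < n; ++v)
          if (!done[v] && dist[v] < best) { best = dist[v]; u = v; }
        if (u < 0) break;
        done[u] = 1;
        for (int v = 0; v < n; ++v) {
          double l = len[u * n + v];
          if (!done[v] && R_FINITE(l) && dist[u] + l < dist[v])
            dist[v] = dist[u] + l;
        }
      }
      for (int v = 0; v < n; ++v)
        if (v != s && R_FINITE(dist[v])) { dsum += dist[v]; ++dcount; }
    }
    out(t, 1) = dcount ? dsum / dcount : R_PosInf;
  }
  return out;
}

// In-place accumulation of per-frequency cross-products into a flat
// CSD matrix: acc(f, j*nc + i) += X(f, i) * conj(X(f, j)). `acc` must
// be a freshly allocated (unshared) complex matrix; mutating it in
// place avoids re-allocating nf x nc^2 temporaries per epoch.
// [[Rcpp::export]]
void cpp_csd_acc(ComplexMatrix acc, ComplexMatrix X) {
  const int nf = X.nrow(), nc = X.ncol();
  if (acc.nrow() != nf || acc.ncol() != nc * nc)
    stop("acc has wrong shape");
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nc; ++i) {
      const int col = j * nc + i;
      for (int f = 0; f < nf; ++f) {
        const Rcomplex a = X(f, i), b = X(f, j);
        acc(f, col).r += a.r * b.r + a.i * b.i;
        acc(f, col).i += a.i * b.r - a.r * b.i;
      }
    }
  }
}
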