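// Unweighted undirected graph routines for the sparsity-sweep metrics.
// Adjacency is a 0/1 integer matrix with zero diagonal. All shortest paths
// are BFS; betweenness is Brandes' algorithm with even splitting over
// equal-length geodesics. Rewiring uses R's RNG so set.seed() governs it.

#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

static std::vector<std::vector<int>> adj_list(const IntegerMatrix& A) {
  int n = A.nrow();
  std::vector<std::vector<int>> nb(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (A(i, j) != 0 && i != j) nb[i].push_back(j);
  return nb;
}

// single-source BFS distances; -1 = unreachable
static void bfs(const std::vector<std::vector<int>>& nb, int s,
                std::vector<int>& dist) {
  std::fill(dist.begin(), dist.end(), -1);
  dist[s] = 0;
  std::queue<int> q;
  q.push(s);
  while (!q.empty()) {
    int u = q.front(); q.pop();
    for (int v : nb[u]) if (dist[v] < 0) { dist[v] = dist[u] + 1; q.push(v); }
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_bfs_distances(IntegerMatrix A) {
  int n = A.nrow();
  auto nb = adj_list(A);
  IntegerMatrix D(n, n);
  std::vector<int> dist(n);
  for (int s = 0; s < n; ++s) {
    bfs(nb, s, dist);
    for (int t = 0; t < n; ++t) D(s, t) = dist[t];
  }
  return D;
}

// per-node triangle counts and degrees -> local clustering
// [[Rcpp::export]]
NumericVector cpp_local_clustering(IntegerMatrix A) {
  int n = A.nrow();
  auto nb = adj_list(A);
  NumericVector cc(n);
  for (int i = 0; i < n; ++i) {
    int k = (int) nb[i].size();
    if (k < 2) { cc[i] = 0.0; continue; }
    int tri = 0;
    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b)
        if (A(nb[i][a], nb[i][b]) != 0) ++tri;
    cc[i] = 2.0 * tri / ((double) k * (k - 1));
  }
  return cc;
}

// Cp (mean local clustering, isolates count as 0) and Lp (mean shortest
// path over connected ordered pairs) in one pass; used per rewired reference.
// [[Rcpp::export]]
NumericVector cpp_cp_lp(IntegerMatrix A) {
  int n = A.nrow();
  auto nb = adj_list(A);
  double cp = 0.0;
  for (int i = 0; i < n; ++i) {
    int k = (int) nb[i].size();
    if (k < 2) continue;
    int tri = 0;
    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b)
        if (A(nb[i][a], nb[i][b]) != 0) ++tri;
    cp += 2.0 * tri / ((double) k * (k - 1));
  }
  cp /= n;
  std::vector<int> dist(n);
  double lsum = 0.0;
  long long npairs = 0;
  for (int s = 0; s < n; ++s) {
    bfs(nb, s, dist);
    for (int t = 0; t < n; ++t)
      if (t != s && dist[t] > 0) { lsum += dist[t]; ++npairs; }
  }
  double lp = npairs > 0 ? lsum / npairs : NA_REAL;
  return NumericVector::create(cp, lp);
}

// global efficiency and per-node efficiency from BFS distances
// [[Rcpp::export]]
List cpp_efficiency(IntegerMatrix A) {
  int n = A.nrow();
  auto nb = adj_list(A);
  std::vector<int> dist(n);
  NumericVector nodal(n);
  double tot = 0.0;
  for (int s = 0; s < n; ++s) {
    bfs(nb, s, dist);
    double acc = 0.0;
    for (int t = 0; t < n; ++t)
      if (t != s && dist[t] > 0) acc += 1.0 / dist[t];
    nodal[s] = n > 1 ? acc / (n - 1) : 0.0;
    tot += acc;
  }
  double eglob = n > 1 ? tot / ((double) n * (n - 1)) : 0.0;
  return List::create(_["eglob"] = eglob, _["nodal_efficiency"] = nodal);
}

// local efficiency: mean over nodes of the global efficiency of the subgraph
// induced by each node's neighbors (< 2 neighbors contributes 0)
// [[Rcpp::export]]
double cpp_local_efficiency(IntegerMatrix A) {
  int n = A.nrow();
  auto nb = adj_list(A);
  double tot = 0.0;
  for (int i = 0; i < n; ++i) {
    int k = (int) nb[i].size();
    if (k < 2) continue;
    // induced subgraph on nb[i]
    std::vector<std::vector<int>> sub(k);
    for (int a = 0; a < k; ++a)
      for (int b = 0; b < k; ++b)
        if (a != b && A(nb[i][a], nb[i][b]) != 0) sub[a].push_back(b);
    std::vector<int> dist(k);
    double acc = 0.0;
    for (int s = 0; s < k; ++s) {
      std::fill(dist.begin(), dist.end(), -1);
      dist[s] = 0;
      std::queue<int> q; q.push(s);
      while (!q.empty()) {
        int u = q.front(); q.pop();
        for (int v : sub[u]) if (dist[v] < 0) { dist[v] = dist[u] + 1; q.push(v); }
      }
      for (int t = 0; t < k; ++t)
        if (t != s && dist[t] > 0) acc += 1.0 / dist[t];
    }
    tot += acc / ((double) k * (k - 1));
  }
  return tot / n;
}

// Brandes betweenness, undirected, unnormalized, each unordered pair once
// [[Rcpp::export]]
NumericVector cpp_betweenness(IntegerMatrix A) {
  int n = A.nrow();
  auto nb = adj_list(A);
  NumericVector bc(n);
  std::vector<int> dist(n), sigma(n);
  std::vector<double> delta(n);
  std::vector<std::vector<int>> pred(n);
  std::vector<int> stack;
  stack.reserve(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    std::fill(sigma.begin(), sigma.end(), 0);
    std::fill(delta.begin(), delta.end(), 0.0);
    for (auto& p : pred) p.clear();
    stack.clear();
    dist[s] = 0; sigma[s] = 1;
    std::queue<int> q; q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      stack.push_back(u);
      for (int v : nb[u]) {
        if (dist[v] < 0) { dist[v] = dist[u] + 1; q.push(v); }
        if (dist[v] == dist[u] + 1) { sigma[v] += sigma[u]; pred[v].push_back(u); }
      }
    }
    for (int i = (int) stack.size() - 1; i >= 0; --i) {
      int w = stack[i];
      for (int u : pred[w])
        delta[u] += ((double) sigma[u] / sigma[w]) * (1.0 + delta[w]);
      if (w != s) bc[w] += delta[w];
    }
  }
  for (int i = 0; i < n; ++i) bc[i] /= 2.0;  // each unordered pair counted twice
  return bc;
}

// Maslov-Sneppen degree-preserving rewiring: `attempts` random double-edge
// swaps; swaps violating simplicity or degree preservation are skipped.
// Draws from R's RNG stream.
// [[Rcpp::export]]
IntegerMatrix cpp_rewire(IntegerMatrix A, int attempts) {
  int n = A.nrow();
  IntegerMatrix B(clone(A));
  std::vector<std::pair<int,int>> edges;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (B(i, j) != 0) edges.push_back({i, j});
  int m = (int) edges.size();
  if (m < 2) return B;
  for (int it = 0; it < attempts; ++it) {
    int e1 = (int) (unif_rand() * m);
    int e2 = (int) (unif_rand() * m);
    if (e1 == e2) continue;
    int a = edges[e1].first, b = edges[e1].second;
    int c = edges[e2].first, d = edges[e2].second;
    // randomly orient the second edge so both pairings are reachable
    if (unif_rand() < 0.5) std::swap(c, d);
    if (a == c || a == d || b == c || b == d) continue;
    if (B(a, d) != 0 || B(c, b) != 0) continue;
    B(a, b) = B(b, a) = 0;
    B(c, d) = B(d, c) = 0;
    B(a, d) = B(d, a) = 1;
    B(c, b) = B(b, c) = 1;
    edges[e1] = {std::min(a, d), std::max(a, d)};
    edges[e2] = {std::min(c, b), std::max(c, b)};
  }
  return B;
}
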