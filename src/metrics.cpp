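// Binary undirected graph kernels for structural covariance networks.
// Conventions throughout (GAT / Rubinov-Sporns style, binary graphs only):
//   - nodes of degree < 2 contribute 0 to clustering and local efficiency;
//   - characteristic path length is defined only on connected graphs (NA
//     otherwise); global efficiency counts unreachable pairs as 0;
//   - betweenness is the unnormalized Brandes pair-fraction sum, endpoints
//     excluded.
#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

typedef std::vector<std::vector<int> > AdjList;

static AdjList adj_from_matrix(const IntegerMatrix& A) {
  int n = A.nrow();
  if (A.ncol() != n) stop("adjacency matrix must be square");
  AdjList adj(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && A(i, j) != 0) adj[i].push_back(j);
  return adj;
}

// BFS distances from src; -1 = unreachable. `qbuf` is caller-provided
// scratch of length >= n (array queue: no heap churn in hot loops).
static void bfs(const AdjList& adj, int src, std::vector<int>& dist,
                std::vector<int>& qbuf) {
  std::fill(dist.begin(), dist.end(), -1);
  dist[src] = 0;
  int head = 0, tail = 0;
  qbuf[tail++] = src;
  while (head < tail) {
    int u = qbuf[head++];
    const std::vector<int>& au = adj[u];
    for (size_t k = 0; k < au.size(); ++k) {
      int v = au[k];
      if (dist[v] < 0) { dist[v] = dist[u] + 1; qbuf[tail++] = v; }
    }
  }
}

static int n_components(const AdjList& adj) {
  int n = adj.size(), ncomp = 0;
  std::vector<int> seen(n, 0);
  std::vector<int> stack;
  for (int s = 0; s < n; ++s) {
    if (seen[s]) continue;
    ++ncomp;
    stack.push_back(s); seen[s] = 1;
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      for (size_t k = 0; k < adj[u].size(); ++k)
        if (!seen[adj[u][k]]) { seen[adj[u][k]] = 1; stack.push_back(adj[u][k]); }
    }
  }
  return ncomp;
}

// local clustering (triangles / possible neighbor pairs) and transitivity
static void triangle_stats(const AdjList& adj, const std::vector<char>& amat,
                           int n, std::vector<double>& ci, double& transit) {
  double tri2 = 0.0, triples = 0.0;  // tri2 = 2*triangles per node summed
  ci.assign(n, 0.0);
  for (int i = 0; i < n; ++i) {
    int k = adj[i].size();
    if (k < 2) continue;
    int links = 0;  // edges among neighbors of i
    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b)
        if (amat[(size_t)adj[i][a] * n + adj[i][b]]) ++links;
    ci[i] = 2.0 * links / ((double)k * (k - 1));
    tri2 += 2.0 * links;           // = number of closed triples centred at i
    triples += (double)k * (k - 1); // ordered open+closed triples centred at i
  }
  transit = (triples > 0.0) ? tri2 / triples : 0.0;
}

// global efficiency of the subgraph induced on node ids `sub`; BFS runs
// directly over the induced vertex list with amat lookups, using scratch
// buffers of length >= n (no allocation)
static double subgraph_efficiency(const int* sub, int m,
                                  const std::vector<char>& amat, int n,
                                  std::vector<int>& dist,
                                  std::vector<int>& qbuf) {
  if (m < 2) return 0.0;
  double acc = 0.0;
  for (int p = 0; p < m; ++p) {
    for (int q = 0; q < m; ++q) dist[q] = -1;
    dist[p] = 0;
    int head = 0, tail = 0;
    qbuf[tail++] = p;
    while (head < tail) {
      int u = qbuf[head++];
      const char* row = &amat[(size_t)sub[u] * n];
      for (int v = 0; v < m; ++v)
        if (dist[v] < 0 && row[sub[v]]) { dist[v] = dist[u] + 1; qbuf[tail++] = v; }
    }
    for (int q = 0; q < m; ++q)
      if (q != p && dist[q] > 0) acc += 1.0 / dist[q];
  }
  return acc / ((double)m * (m - 1));
}

static void global_metrics(const AdjList& adj, const std::vector<char>& amat,
                           int n, double* out) {
  // out: C, T, Eloc, Eglob, L, ncomp
  std::vector<double> ci;
  double transit;
  triangle_stats(adj, amat, n, ci, transit);
  double C = 0.0;
  for (int i = 0; i < n; ++i) C += ci[i];
  C = (n > 0) ? C / n : 0.0;

  std::vector<int> dist(n), qbuf(n);
  double Eloc = 0.0;
  for (int i = 0; i < n; ++i)
    if ((int)adj[i].size() >= 2)
      Eloc += subgraph_efficiency(adj[i].data(), adj[i].size(), amat, n,
                                  dist, qbuf);
  Eloc = (n > 0) ? Eloc / n : 0.0;

  double einv = 0.0, dsum = 0.0;
  long npairs = (long)n * (n - 1);
  bool connected = true;
  for (int i = 0; i < n; ++i) {
    bfs(adj, i, dist, qbuf);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (dist[j] > 0) { einv += 1.0 / dist[j]; dsum += dist[j]; }
      else connected = false;
    }
  }
  double Eglob = (npairs > 0) ? einv / npairs : 0.0;
  double L = (connected && npairs > 0) ? dsum / npairs : NA_REAL;
  out[0] = C; out[1] = transit; out[2] = Eloc; out[3] = Eglob; out[4] = L;
  out[5] = (double)n_components(adj);
}

static std::vector<char> flat_from_matrix(const IntegerMatrix& A) {
  int n = A.nrow();
  std::vector<char> amat((size_t)n * n, 0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && A(i, j) != 0) amat[(size_t)i * n + j] = 1;
  return amat;
}

// [[Rcpp::export]]
IntegerMatrix cpp_all_pairs_dist(IntegerMatrix A) {
  int n = A.nrow();
  AdjList adj = adj_from_matrix(A);
  IntegerMatrix D(n, n);
  std::vector<int> dist(n), qbuf(n);
  for (int i = 0; i < n; ++i) {
    bfs(adj, i, dist, qbuf);
    for (int j = 0; j < n; ++j) D(i, j) = dist[j];
  }
  return D;
}

// [[Rcpp::export]]
int cpp_n_components(IntegerMatrix A) {
  AdjList adj = adj_from_matrix(A);
  return n_components(adj);
}

// [[Rcpp::export]]
List cpp_triangle_stats(IntegerMatrix A) {
  int n = A.nrow();
  AdjList adj = adj_from_matrix(A);
  std::vector<char> amat = flat_from_matrix(A);
  std::vector<double> ci;
  double transit;
  triangle_stats(adj, amat, n, ci, transit);
  return List::create(_["local"] = wrap(ci), _["transitivity"] = transit);
}

// [[Rcpp::export]]
NumericVector cpp_local_efficiency(IntegerMatrix A) {
  int n = A.nrow();
  AdjList adj = adj_from_matrix(A);
  std::vector<char> amat = flat_from_matrix(A);
  NumericVector e(n);
  std::vector<int> dist(n), qbuf(n);
  for (int i = 0; i < n; ++i)
    e[i] = ((int)adj[i].size() >= 2)
      ? subgraph_efficiency(adj[i].data(), adj[i].size(), amat, n, dist, qbuf)
      : 0.0;
  return e;
}

// [[Rcpp::export]]
NumericVector cpp_global_metrics(IntegerMatrix A) {
  int n = A.nrow();
  AdjList adj = adj_from_matrix(A);
  std::vector<char> amat = flat_from_matrix(A);
  double out[6];
  global_metrics(adj, amat, n, out);
  NumericVector res = NumericVector::create(
    _["clustering"] = out[0], _["transitivity"] = out[1],
    _["local_efficiency"] = out[2], _["global_efficiency"] = out[3],
    _["path_length"] = out[4], _["n_components"] = out[5]);
  return res;
}

static std::vector<double> brandes(const AdjList& adj, int n) {
  std::vector<double> bc(n, 0.0);
  std::vector<int> dist(n), sigma(n), stack_order;
  std::vector<double> delta(n);
  std::vector<std::vector<int> > pred(n);
  stack_order.reserve(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    std::fill(sigma.begin(), sigma.end(), 0);
    std::fill(delta.begin(), delta.end(), 0.0);
    for (int i = 0; i < n; ++i) pred[i].clear();
    stack_order.clear();
    dist[s] = 0; sigma[s] = 1;
    size_t head = 0;
    stack_order.push_back(s);
    while (head < stack_order.size()) {
      int u = stack_order[head++];
      for (size_t k = 0; k < adj[u].size(); ++k) {
        int v = adj[u][k];
        if (dist[v] < 0) { dist[v] = dist[u] + 1; stack_order.push_back(v); }
        if (dist[v] == dist[u] + 1) { sigma[v] += sigma[u]; pred[v].push_back(u); }
      }
    }
    for (int k = (int)stack_order.size() - 1; k >= 0; --k) {
      int w = stack_order[k];
      for (size_t p = 0; p < pred[w].size(); ++p) {
        int u = pred[w][p];
        delta[u] += ((double)sigma[u] / sigma[w]) * (1.0 + delta[w]);
      }
      if (w != s) bc[w] += delta[w];
    }
  }
  for (int i = 0; i < n; ++i) bc[i] /= 2.0;  // undirected: each pair counted twice
  return bc;
}

// [[Rcpp::export]]
NumericVector cpp_betweenness(IntegerMatrix A) {
  AdjList adj = adj_from_matrix(A);
  return wrap(brandes(adj, A.nrow()));
}

// Degree-preserving double-edge-swap rewiring (Maslov-Sneppen).
// Performs up to `nswap` successful swaps within an attempt budget of
// 100*nswap; uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_rewire(IntegerMatrix A, int nswap) {
  int n = A.nrow();
  std::vector<char> amat = flat_from_matrix(A);
  std::vector<int> ei, ej;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (amat[(size_t)i * n + j]) { ei.push_back(i); ej.push_back(j); }
  int E = ei.size();
  int done = 0;
  if (E >= 2) {
    long budget = 100L * (nswap > 0 ? nswap : 1);
    for (long att = 0; att < budget && done < nswap; ++att) {
      int e1 = (int)(unif_rand() * E), e2 = (int)(unif_rand() * E);
      if (e1 == e2) continue;
      int a = ei[e1], b = ej[e1], c = ei[e2], d = ej[e2];
      if (unif_rand() < 0.5) std::swap(c, d);  // randomize orientation
      // proposed edges (a,d) and (c,b)
      if (a == d || c == b) continue;
      if (a == c || b == d) continue;          // would duplicate an endpoint pair
      if (amat[(size_t)a * n + d] || amat[(size_t)c * n + b]) continue;
      amat[(size_t)a * n + b] = amat[(size_t)b * n + a] = 0;
      amat[(size_t)c * n + d] = amat[(size_t)d * n + c] = 0;
      amat[(size_t)a * n + d] = amat[(size_t)d * n + a] = 1;
      amat[(size_t)c * n + b] = amat[(size_t)b * n + c] = 1;
      ei[e1] = std::min(a, d); ej[e1] = std::max(a, d);
      ei[e2] = std::min(c, b); ej[e2] = std::max(c, b);
      ++done;
    }
  }
  IntegerMatrix out(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      out(i, j) = amat[(size_t)i * n + j] ? 1 : 0;
  return List::create(_["adjacency"] = out, _["n_swaps"] = done);
}

// Global metrics along a nested density sweep. Edges (ei, ej; 1-based) are
// ordered by decreasing correlation; mvec gives the cumulative edge count at
// each density. Returns one row per density:
// C, T, Eloc, Eglob, L (NA if fragmented), n_components.
// [[Rcpp::export]]
NumericMatrix cpp_density_sweep(int n, IntegerVector ei, IntegerVector ej,
                                IntegerVector mvec) {
  int nd = mvec.size(), E = ei.size();
  AdjList adj(n);
  std::vector<char> amat((size_t)n * n, 0);
  NumericMatrix out(nd, 6);
  colnames(out) = CharacterVector::create("clustering", "transitivity",
    "local_efficiency", "global_efficiency", "path_length", "n_components");
  int added = 0;
  double res[6];
  for (int d = 0; d < nd; ++d) {
    int m = mvec[d];
    if (m > E) m = E;
    for (; added < m; ++added) {
      int a = ei[added] - 1, b = ej[added] - 1;
      if (amat[(size_t)a * n + b]) continue;
      amat[(size_t)a * n + b] = amat[(size_t)b * n + a] = 1;
      adj[a].push_back(b); adj[b].push_back(a);
    }
    global_metrics(adj, amat, n, res);
    for (int k = 0; k < 6; ++k) out(d, k) = res[k];
  }
  return out;
}

// Nodal degree and betweenness along the same nested sweep.
// [[Rcpp::export]]
List cpp_density_sweep_nodal(int n, IntegerVector ei, IntegerVector ej,
                             IntegerVector mvec) {
  int nd = mvec.size(), E = ei.size();
  AdjList adj(n);
  std::vector<char> amat((size_t)n * n, 0);
  NumericMatrix deg(n, nd), btw(n, nd);
  int added = 0;
  for (int d = 0; d < nd; ++d) {
    int m = mvec[d];
    if (m > E) m = E;
    for (; added < m; ++added) {
      int a = ei[added] - 1, b = ej[added] - 1;
      if (amat[(size_t)a * n + b]) continue;
      amat[(size_t)a * n + b] = amat[(size_t)b * n + a] = 1;
      adj[a].push_back(b); adj[b].push_back(a);
    }
    std::vector<double> bc = brandes(adj, n);
    for (int i = 0; i < n; ++i) {
      deg(i, d) = (double)adj[i].size();
      btw(i, d) = bc[i];
    }
  }
  return List::create(_["degree"] = deg, _["betweenness"] = btw);
}
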