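#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Shortest-path kernels for small dense pen networks (n <= ~30 animals).
// O(n^2) Dijkstra per source is optimal at this scale. Edge lengths are
// positive reals (1/weight for weighted networks, 1 for binary ones);
// equal-length path ties are detected with an absolute tolerance because
// sums like 1/3 + 1/3 + 1/3 are not exact in doubles.

static const double TIE_EPS = 1e-10;

struct Adj {
  std::vector<std::vector<int>> nbr;
  std::vector<std::vector<double>> len;
  Adj(int n, const IntegerVector& from, const IntegerVector& to,
      const NumericVector& l) : nbr(n), len(n) {
    for (int e = 0; e < from.size(); ++e) {
      nbr[from[e]].push_back(to[e]);
      len[from[e]].push_back(l[e]);
    }
  }
};

// Dijkstra from s; fills dist. When sigma/preds/order are non-null it also
// counts shortest paths and records the settle order (for Brandes).
static void dijkstra(int n, const Adj& adj, int s,
                     std::vector<double>& dist,
                     std::vector<double>* sigma,
                     std::vector<std::vector<int>>* preds,
                     std::vector<int>* order) {
  const double INF = R_PosInf;
  dist.assign(n, INF);
  std::vector<bool> done(n, false);
  dist[s] = 0.0;
  if (sigma) { sigma->assign(n, 0.0); (*sigma)[s] = 1.0; }
  if (preds) { preds->assign(n, std::vector<int>()); }
  if (order) order->clear();

  for (int it = 0; it < n; ++it) {
    int u = -1;
    double best = INF;
    for (int v = 0; v < n; ++v)
      if (!done[v] && dist[v] < best) { best = dist[v]; u = v; }
    if (u < 0) break;
    done[u] = true;
    if (order) order->push_back(u);
    for (size_t k = 0; k < adj.nbr[u].size(); ++k) {
      int v = adj.nbr[u][k];
      double nd = dist[u] + adj.len[u][k];
      if (nd < dist[v] - TIE_EPS) {
        dist[v] = nd;
        if (sigma) (*sigma)[v] = (*sigma)[u];
        if (preds) { (*preds)[v].clear(); (*preds)[v].push_back(u); }
      } else if (std::abs(nd - dist[v]) <= TIE_EPS) {
        if (sigma) (*sigma)[v] += (*sigma)[u];
        if (preds) (*preds)[v].push_back(u);
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_pairwise_distances(int n, IntegerVector from,
                                     IntegerVector to, NumericVector len) {
  Adj adj(n, from, to, len);
  NumericMatrix d(n, n);
  std::vector<double> dist;
  for (int s = 0; s < n; ++s) {
    dijkstra(n, adj, s, dist, nullptr, nullptr, nullptr);
    for (int t = 0; t < n; ++t) d(s, t) = dist[t];
  }
  return d;
}

// Brandes (2001) betweenness with path counting over tied shortest paths;
// returns the raw (unnormalized) sum over ordered pairs.
// [[Rcpp::export]]
NumericVector cpp_betweenness(int n, IntegerVector from, IntegerVector to,
                              NumericVector len) {
  Adj adj(n, from, to, len);
  NumericVector bc(n);
  std::vector<double> dist, sigma, delta(n);
  std::vector<std::vector<int>> preds;
  std::vector<int> order;
  for (int s = 0; s < n; ++s) {
    dijkstra(n, adj, s, dist, &sigma, &preds, &order);
    std::fill(delta.begin(), delta.end(), 0.0);
    for (int i = (int)order.size() - 1; i >= 0; --i) {
      int w = order[i];
      for (int u : preds[w])
        delta[u] += (sigma[u] / sigma[w]) * (1.0 + delta[w]);
      if (w != s) bc[w] += delta[w];
    }
  }
  return bc;
}
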