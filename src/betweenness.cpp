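#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Brandes accumulation for unweighted undirected graphs.
// Convention: unordered source/target pairs, fractional dependencies,
// endpoints excluded, no normalization. Edges are 0-based endpoint vectors.
// [[Rcpp::export(name = ".brandes_betweenness")]]
NumericVector brandes_betweenness(int n, IntegerVector from, IntegerVector to) {
  std::vector< std::vector<int> > adj(n);
  int m = from.size();
  for (int e = 0; e < m; ++e) {
    adj[from[e]].push_back(to[e]);
    adj[to[e]].push_back(from[e]);
  }
  NumericVector bc(n);
  std::vector<int> dist(n), order;
  std::vector<double> sigma(n), delta(n);
  std::vector< std::vector<int> > pred(n);
  order.reserve(n);

  for (int s = 0; s < n; ++s) {
    order.clear();
    for (int v = 0; v < n; ++v) {
      dist[v] = -1; sigma[v] = 0.0; delta[v] = 0.0; pred[v].clear();
    }
    dist[s] = 0; sigma[s] = 1.0;
    std::queue<int> q;
    q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      order.push_back(v);
      for (size_t i = 0; i < adj[v].size(); ++i) {
        int w = adj[v][i];
        if (dist[w] < 0) {
          dist[w] = dist[v] + 1;
          q.push(w);
        }
        if (dist[w] == dist[v] + 1) {
          sigma[w] += sigma[v];
          pred[w].push_back(v);
        }
      }
    }
    for (int i = (int) order.size() - 1; i >= 0; --i) {
      int w = order[i];
      for (size_t j = 0; j < pred[w].size(); ++j) {
        int v = pred[w][j];
        delta[v] += sigma[v] / sigma[w] * (1.0 + delta[w]);
      }
      if (w != s) bc[w] += delta[w];
    }
  }
  // each unordered pair is visited from both endpoints
  for (int v = 0; v < n; ++v) bc[v] /= 2.0;
  return bc;
}
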