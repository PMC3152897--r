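#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exhaustive maximum of Newman-Girvan modularity over all set partitions of
// the node set, enumerated as restricted growth strings. Brute-force
// reference for small graphs (n <= 12); independent of any greedy search.
// [[Rcpp::export(name = ".exhaustive_modularity_max")]]
List exhaustive_modularity_max(int n, IntegerVector from, IntegerVector to) {
  if (n > 12) stop("exhaustive search is limited to n <= 12 nodes");
  int m = from.size();
  if (m == 0) stop("graph has no edges");
  std::vector<int> deg(n, 0);
  for (int e = 0; e < m; ++e) { deg[from[e]]++; deg[to[e]]++; }

  std::vector<int> a(n, 0);   // restricted growth string
  double bestQ = -2.0;
  std::vector<int> best(n, 0);
  const double m2 = 2.0 * m;

  std::vector<double> ec(n), dc(n);
  for (;;) {
    // evaluate current partition
    std::fill(ec.begin(), ec.end(), 0.0);
    std::fill(dc.begin(), dc.end(), 0.0);
    for (int v = 0; v < n; ++v) dc[a[v]] += deg[v];
    for (int e = 0; e < m; ++e)
      if (a[from[e]] == a[to[e]]) ec[a[from[e]]] += 1.0;
    double Q = 0.0;
    for (int c = 0; c < n; ++c)
      if (dc[c] > 0.0 || ec[c] > 0.0)
        Q += ec[c] / m - (dc[c] / m2) * (dc[c] / m2);
    if (Q > bestQ) { bestQ = Q; best = a; }

    // next restricted growth string: a[i] may rise to 1 + max(a[0..i-1])
    int i = n - 1;
    while (i > 0) {
      int mx = 0;
      for (int k = 0; k < i; ++k) if (a[k] > mx) mx = a[k];
      if (a[i] <= mx) break;
      --i;
    }
    if (i == 0) break;
    a[i]++;
    for (int j = i + 1; j < n; ++j) a[j] = 0;
  }
  return List::create(_["Q"] = bestQ,
                      _["assignment"] = IntegerVector(best.begin(), best.end()) + 1);
}
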