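#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Depth-limited recursive visit of simple paths from one source node.
// A target u contributes every time it is reached at depth == tsp_src[u]
// (i.e. along a topological shortest path); the accumulated geometrical
// projection of the path is added to sum[u]. Without DAG pruning every
// neighbor is expanded (the k^L recursion tree analysed by the complexity
// profile); with dag = true descent is restricted to neighbors one BFS level
// deeper, which cannot change the recorded statistics because every prefix
// of a shortest path is itself a shortest path.
static void rec_visit(int v, int depth, double acc,
                      const std::vector<std::vector<int>>& adj,
                      const NumericMatrix& w,
                      const IntegerVector& tsp_src, int L,
                      const LogicalVector& record, bool dag,
                      std::vector<char>& onpath,
                      std::vector<double>& cnt, std::vector<double>& sum) {
  const int nd = depth + 1;
  const std::vector<int>& nb = adj[v];
  for (size_t k = 0; k < nb.size(); ++k) {
    const int u = nb[k];
    if (onpath[u]) continue;
    if (dag && tsp_src[u] != nd) continue;
    const double a2 = acc + w(v, u);
    if (tsp_src[u] == nd && record[u]) { cnt[u] += 1.0; sum[u] += a2; }
    if (nd < L) {
      onpath[u] = 1;
      rec_visit(u, nd, a2, adj, w, tsp_src, L, record, dag, onpath, cnt, sum);
      onpath[u] = 0;
    }
  }
}

// Enumerate all topological shortest paths from `source` (0-based) up to
// recursion depth L, returning per-node path counts and projection sums for
// the nodes flagged in `record`.
// [[Rcpp::export]]
List ptsp_enumerate_source(List adjlist, NumericMatrix w, IntegerVector tsp_src,
                           int source, int L, LogicalVector record, bool dag) {
  const int n = adjlist.size();
  std::vector<std::vector<int>> adj(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = adjlist[i];
    adj[i].assign(v.begin(), v.end());
  }
  std::vector<char> onpath(n, 0);
  std::vector<double> cnt(n, 0.0), sum(n, 0.0);
  onpath[source] = 1;
  if (L > 0)
    rec_visit(source, 0, 0.0, adj, w, tsp_src, L, record, dag, onpath, cnt, sum);
  return List::create(_["count"] = NumericVector(cnt.begin(), cnt.end()),
                      _["sum"] = NumericVector(sum.begin(), sum.end()));
}
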