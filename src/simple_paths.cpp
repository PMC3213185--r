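#include <Rcpp.h>
#include <vector>

// Exact count of directed simple paths (no repeated vertex) from src to dst
// by depth-first search with on-path marking. Counts only; memory O(V).
// Vertices are 1-based; edges given as from/to integer vectors.

static void dfs(int u, int dst,
                const std::vector<int> &off, const std::vector<int> &adj,
                std::vector<char> &onpath, double &count) {
  if (u == dst) {
    count += 1.0;
    return;
  }
  onpath[u] = 1;
  for (int k = off[u]; k < off[u + 1]; ++k) {
    int w = adj[k];
    if (!onpath[w]) dfs(w, dst, off, adj, onpath, count);
  }
  onpath[u] = 0;
}

// [[Rcpp::export]]
double count_simple_paths_cpp(Rcpp::IntegerVector from, Rcpp::IntegerVector to,
                              int n_vertices, int src, int dst) {
  const int n = n_vertices;
  std::vector<int> deg(n + 2, 0), off(n + 2, 0);
  const int m = from.size();
  for (int i = 0; i < m; ++i) deg[from[i]]++;
  for (int v = 1; v <= n; ++v) off[v + 1] = off[v] + deg[v];
  std::vector<int> adj(m), pos(n + 2, 0);
  for (int i = 0; i < m; ++i) {
    int u = from[i];
    adj[off[u] + pos[u]++] = to[i];
  }
  // shift: off[u] .. off[u+1] covers u's edges
  std::vector<char> onpath(n + 1, 0);
  double count = 0.0;
  if (src >= 1 && src <= n && dst >= 1 && dst <= n && src != dst)
    dfs(src, dst, off, adj, onpath, count);
  return count;
}
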