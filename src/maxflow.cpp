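#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Dinic max-flow / min-cut for the binary MRF graphs built by the
// segmentation stages. Vertices 0..n-1 are variables, n is the source,
// n+1 the sink. After max flow, variables reachable from the source in the
// residual graph form the foreground (source) side of a minimum cut.

struct Arc {
  int to;
  double cap;
  int rev; // index of reverse arc in adj[to]
};

class Dinic {
public:
  int n;
  std::vector<std::vector<Arc>> adj;
  std::vector<int> level, iter;
  explicit Dinic(int n_) : n(n_), adj(n_), level(n_), iter(n_) {}
  void add_edge(int a, int b, double cap_ab, double cap_ba) {
    Arc f{b, cap_ab, (int)adj[b].size()};
    Arc r{a, cap_ba, (int)adj[a].size()};
    adj[a].push_back(f);
    adj[b].push_back(r);
  }
  bool bfs(int s, int t) {
    std::fill(level.begin(), level.end(), -1);
    std::queue<int> q;
    level[s] = 0;
    q.push(s);
    while (!q.empty()) {
      int v = q.front();
      q.pop();
      for (const Arc &a : adj[v])
        if (a.cap > 1e-12 && level[a.to] < 0) {
          level[a.to] = level[v] + 1;
          q.push(a.to);
        }
    }
    return level[t] >= 0;
  }
  double dfs(int v, int t, double f) {
    if (v == t) return f;
    for (int &i = iter[v]; i < (int)adj[v].size(); ++i) {
      Arc &a = adj[v][i];
      if (a.cap > 1e-12 && level[v] < level[a.to]) {
        double d = dfs(a.to, t, std::min(f, a.cap));
        if (d > 0) {
          a.cap -= d;
          adj[a.to][a.rev].cap += d;
          return d;
        }
      }
    }
    return 0.0;
  }
  double run(int s, int t) {
    double flow = 0.0;
    while (bfs(s, t)) {
      std::fill(iter.begin(), iter.end(), 0);
      double f;
      while ((f = dfs(s, t, R_PosInf)) > 0) flow += f;
    }
    return flow;
  }
};

// cost_fg / cost_bg: terminal capacities per variable (v -> t resp. s -> v);
// edges: m x 2 (1-based variable ids); w: n-link capacity (symmetric).
// Returns logical: TRUE = foreground (source side).
// [[Rcpp::export]]
LogicalVector cpp_mincut(NumericVector cost_fg, NumericVector cost_bg,
                         IntegerMatrix edges, NumericVector w) {
  int n = cost_fg.size();
  int s = n, t = n + 1;
  Dinic g(n + 2);
  for (int v = 0; v < n; ++v) {
    if (cost_bg[v] > 0) g.add_edge(s, v, cost_bg[v], 0.0);
    if (cost_fg[v] > 0) g.add_edge(v, t, cost_fg[v], 0.0);
  }
  for (int e = 0; e < edges.nrow(); ++e)
    g.add_edge(edges(e, 0) - 1, edges(e, 1) - 1, w[e], w[e]);
  g.run(s, t);
  // source side by BFS on the residual graph
  LogicalVector fg(n, false);
  std::vector<char> vis(n + 2, 0);
  std::queue<int> q;
  vis[s] = 1;
  q.push(s);
  while (!q.empty()) {
    int v = q.front();
    q.pop();
    for (const Arc &a : g.adj[v])
      if (a.cap > 1e-12 && !vis[a.to]) {
        vis[a.to] = 1;
        q.push(a.to);
      }
  }
  for (int v = 0; v < n; ++v) fg[v] = vis[v];
  return fg;
}
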