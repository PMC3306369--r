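#include <Rcpp.h>
using namespace Rcpp;

// Minimum-change (parsimony) score of an unrooted tree by dynamic programming
// over states at every node (Sankoff with unit costs for unordered characters,
// linear |i-j| costs for ordered/additive ones). Exact on polytomies, which
// plain Fitch intersection/union is not.
//
// edges:   m x 2 integer matrix of undirected edges; tips are 1..n_tip,
//          internal nodes any larger ids (need not be contiguous).
// tipbits: n_tip x n_char integer matrix; bit s set <=> state s observed in
//          that cell (polymorphism = several bits); NA = missing, which
//          contributes the full state universe and never adds steps.
// n_states: size of the global state universe (states 0..n_states-1).
// ordered: per-character flag selecting |i-j| step costs.
//
// Returns a numeric vector of per-character minimum step counts.

static const double BIG = 1e9;

// [[Rcpp::export]]
NumericVector sankoff_score_cpp(IntegerMatrix edges, int n_tip,
                                IntegerMatrix tipbits, int n_states,
                                LogicalVector ordered) {
  const int m = edges.nrow();
  const int n_char = tipbits.ncol();
  NumericVector out(n_char);
  if (m == 0 || n_tip < 2) return out;

  int n_nodes = 0;
  for (int i = 0; i < m; ++i) {
    if (edges(i, 0) > n_nodes) n_nodes = edges(i, 0);
    if (edges(i, 1) > n_nodes) n_nodes = edges(i, 1);
  }

  // adjacency lists
  std::vector<std::vector<int> > adj(n_nodes + 1);
  for (int i = 0; i < m; ++i) {
    adj[edges(i, 0)].push_back(edges(i, 1));
    adj[edges(i, 1)].push_back(edges(i, 0));
  }

  // root the traversal at the neighbour of tip 1 (any node works: the
  // parsimony score of an unrooted tree is invariant to root placement)
  int root = adj[1].empty() ? 1 : adj[1][0];
  if (n_tip == 2 && m == 1) root = 1;  // two-tip tree: root at tip 1

  // iterative DFS -> postorder node list + parent pointers
  std::vector<int> post;  post.reserve(n_nodes);
  std::vector<int> parent(n_nodes + 1, 0);
  std::vector<int> stack;  stack.push_back(root);
  parent[root] = -1;
  std::vector<int> order;  order.reserve(n_nodes);
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    order.push_back(v);
    for (size_t k = 0; k < adj[v].size(); ++k) {
      int w = adj[v][k];
      if (w != parent[v]) { parent[w] = v; stack.push_back(w); }
    }
  }
  for (int i = (int)order.size() - 1; i >= 0; --i) post.push_back(order[i]);

  std::vector<double> cost((n_nodes + 1) * n_states);

  for (int j = 0; j < n_char; ++j) {
    bool ord = ordered[j];
    // initialise
    for (size_t q = 0; q < post.size(); ++q) {
      int v = post[q];
      double *cv = &cost[v * n_states];
      if (v <= n_tip) {
        int bits = tipbits(v - 1, j);
        if (bits == NA_INTEGER || bits == 0) {
          for (int s = 0; s < n_states; ++s) cv[s] = 0.0;
        } else {
          for (int s = 0; s < n_states; ++s)
            cv[s] = (bits & (1 << s)) ? 0.0 : BIG;
        }
      } else {
        for (int s = 0; s < n_states; ++s) cv[s] = 0.0;
      }
    }
    // postorder accumulation into parents
    for (size_t q = 0; q < post.size(); ++q) {
      int v = post[q];
      int p = parent[v];
      if (p <= 0) continue;
      double *cv = &cost[v * n_states];
      double *cp = &cost[p * n_states];
      for (int s = 0; s < n_states; ++s) {
        double best = BIG * 2;
        for (int t = 0; t < n_states; ++t) {
          double w = ord ? std::abs(s - t) : (s == t ? 0.0 : 1.0);
          double c = cv[t] + w;
          if (c < best) best = c;
        }
        cp[s] += best;
      }
    }
    double best = BIG * 2;
    double *cr = &cost[root * n_states];
    for (int s = 0; s < n_states; ++s) if (cr[s] < best) best = cr[s];
    out[j] = (best >= BIG) ? NA_REAL : best;
  }
  return out;
}
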