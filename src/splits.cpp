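#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Non-trivial splits (bipartitions) of an unrooted tree, each encoded as a
// bitmask over tips (tip i -> bit i-1). Masks are canonicalised to the side
// NOT containing the smallest present tip and returned sorted, so equal
// topologies yield identical vectors. Returned as doubles (exact for up to
// 52 tips, which callers enforce).

static int popcount64(uint64_t x) {
  int c = 0;
  while (x) { x &= x - 1; ++c; }
  return c;
}

// [[Rcpp::export]]
NumericVector ut_splits_cpp(IntegerMatrix edges, int n_tip) {
  const int m = edges.nrow();
  if (m == 0 || n_tip > 52) stop("ut_splits_cpp: need 1..52 tips");
  int n_nodes = 0;
  for (int i = 0; i < m; ++i) {
    if (edges(i, 0) > n_nodes) n_nodes = edges(i, 0);
    if (edges(i, 1) > n_nodes) n_nodes = edges(i, 1);
  }
  std::vector<std::vector<int> > adj(n_nodes + 1);
  for (int i = 0; i < m; ++i) {
    adj[edges(i, 0)].push_back(edges(i, 1));
    adj[edges(i, 1)].push_back(edges(i, 0));
  }
  uint64_t full = 0;
  int ref = 0, ntip_present = 0;
  for (int v = 1; v <= n_tip && v <= n_nodes; ++v) {
    if (!adj[v].empty()) {
      full |= (uint64_t)1 << (v - 1);
      if (!ref) ref = v;
      ++ntip_present;
    }
  }
  if (ntip_present < 4) return NumericVector(0);
  uint64_t refbit = (uint64_t)1 << (ref - 1);

  std::vector<int> parent(n_nodes + 1, 0), order;
  order.reserve(n_nodes);
  std::vector<int> stack;
  stack.push_back(ref);
  parent[ref] = -1;
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    order.push_back(v);
    for (size_t k = 0; k < adj[v].size(); ++k) {
      int w = adj[v][k];
      if (w != parent[v]) { parent[w] = v; stack.push_back(w); }
    }
  }
  std::vector<uint64_t> below(n_nodes + 1, 0);
  for (int i = (int)order.size() - 1; i >= 0; --i) {
    int v = order[i];
    if (v <= n_tip) below[v] = (uint64_t)1 << (v - 1);
    if (parent[v] > 0) below[parent[v]] |= below[v];
  }
  std::vector<uint64_t> keys;
  for (size_t i = 0; i < order.size(); ++i) {
    int v = order[i];
    if (v == ref) continue;
    uint64_t mask = below[v];
    uint64_t other = full & ~mask;
    if (popcount64(mask) < 2 || popcount64(other) < 2) continue;
    keys.push_back((mask & refbit) ? other : mask);
  }
  std::sort(keys.begin(), keys.end());
  keys.erase(std::unique(keys.begin(), keys.end()), keys.end());
  NumericVector out(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) out[i] = (double)keys[i];
  return out;
}
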