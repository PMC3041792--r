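#include <Rcpp.h>
#include <unordered_set>
using namespace Rcpp;

// Degree-preserving randomization of a simple undirected graph by repeated
// double-edge swaps: pick two edges (a,b), (c,d), rewire to (a,d), (c,b);
// reject any proposal creating a self-loop or a multi-edge. Every accepted
// swap preserves each node's degree exactly. Uses R's RNG, so results are
// reproducible under set.seed().
//
// edges: E x 2 integer matrix of 0-based node ids (i < j not required).
// n_attempts: number of attempted swaps.
// Returns the rewired E x 2 edge matrix (0-based).
// [[Rcpp::export]]
IntegerMatrix double_edge_swap_cpp(IntegerMatrix edges, int n_nodes,
                                   double n_attempts) {
  int E = edges.nrow();
  if (E < 2) return edges;
  std::vector<int> u(E), v(E);
  std::unordered_set<long long> present;
  present.reserve(E * 2);
  auto key = [n_nodes](int a, int b) {
    int i = a < b ? a : b, j = a < b ? b : a;
    return (long long)i * n_nodes + j;
  };
  for (int e = 0; e < E; ++e) {
    u[e] = edges(e, 0);
    v[e] = edges(e, 1);
    present.insert(key(u[e], v[e]));
  }
  for (double t = 0; t < n_attempts; ++t) {
    int e1 = (int)(unif_rand() * E);
    int e2 = (int)(unif_rand() * E);
    if (e1 == e2) continue;
    int a = u[e1], b = v[e1], c = u[e2], d = v[e2];
    if (unif_rand() < 0.5) std::swap(c, d); // random swap orientation
    // proposal: (a,b),(c,d) -> (a,d),(c,b)
    if (a == d || c == b) continue;
    if (a == c || b == d) continue;        // would duplicate or no-op
    long long kad = key(a, d), kcb = key(c, b);
    if (present.count(kad) || present.count(kcb)) continue;
    present.erase(key(a, b));
    present.erase(key(c, d));
    present.insert(kad);
    present.insert(kcb);
    v[e1] = d;
    u[e2] = c;
    v[e2] = b;
    u[e1] = a;
  }
  IntegerMatrix out(E, 2);
  for (int e = 0; e < E; ++e) {
    out(e, 0) = u[e] < v[e] ? u[e] : v[e];
    out(e, 1) = u[e] < v[e] ? v[e] : u[e];
  }
  return out;
}
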