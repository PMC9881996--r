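#include <Rcpp.h>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

// Degree-preserving randomization of a simple directed graph by the
// three-edge swap: pick an existing directed 3-path a->b->c->d and rewire
// it to a->c, c->b, b->d. Each node keeps its exact in- and out-degree.
// A proposed move is rejected (graph unchanged, attempt counted) when any
// replacement edge would be a self-loop or already exists.
//
// Selection: a uniformly random edge a->b, then a uniform out-edge b->c of
// b, then a uniform out-edge c->d of c. Because out-degrees are invariant,
// the reverse move (the same pattern applied to a->c->b->d in the rewired
// graph) has identical selection probability, so the chain is symmetric
// and its stationary distribution is uniform over the space of simple
// digraphs with the given degree sequences.
//
// Randomness comes from R's RNG, so results are reproducible via set.seed.

static inline long long edge_key(int u, int v, int n) {
  return static_cast<long long>(u) * n + v;
}

static inline int runif_int(int n) {
  int k = static_cast<int>(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// [[Rcpp::export]]
List swap_kernel_cpp(IntegerVector from, IntegerVector to, int n_nodes,
                     double target_swaps, double max_attempts) {
  int m = from.size();
  if (m < 3)
    stop("three-edge swap needs at least 3 edges");

  std::vector<int> efrom(from.begin(), from.end());
  std::vector<int> eto(to.begin(), to.end());

  // out_edges[u] holds indices into the edge arrays; since a move only
  // retargets edges (sources never change), out-adjacency stays valid.
  std::vector<std::vector<int> > out_edges(n_nodes);
  std::unordered_set<long long> edge_set;
  edge_set.reserve(m * 2);
  for (int e = 0; e < m; ++e) {
    int u = efrom[e], v = eto[e];
    if (u == v) stop("self-loop in input graph");
    if (!edge_set.insert(edge_key(u, v, n_nodes)).second)
      stop("duplicate edge in input graph");
    out_edges[u].push_back(e);
  }

  // Repoint edge e at a new target; source (hence out-adjacency) unchanged.
  auto retarget = [&](int e, int new_to) {
    edge_set.erase(edge_key(efrom[e], eto[e], n_nodes));
    eto[e] = new_to;
    edge_set.insert(edge_key(efrom[e], new_to, n_nodes));
  };

  double swaps = 0, attempts = 0;
  GetRNGstate();
  while (swaps < target_swaps && attempts < max_attempts) {
    attempts += 1;
    int e1 = runif_int(m);                 // a -> b
    int a = efrom[e1], b = eto[e1];
    if (out_edges[b].empty()) continue;
    int e2 = out_edges[b][runif_int(out_edges[b].size())];  // b -> c
    int c = eto[e2];
    if (out_edges[c].empty()) continue;
    int e3 = out_edges[c][runif_int(out_edges[c].size())];  // c -> d
    int d = eto[e3];
    if (e1 == e2 || e2 == e3 || e1 == e3) continue;  // need 3 distinct edges
    // replacements: a->c, c->b, b->d
    if (a == c || b == d) continue;        // would create a self-loop
    if (edge_set.count(edge_key(a, c, n_nodes)) ||
        edge_set.count(edge_key(c, b, n_nodes)) ||
        edge_set.count(edge_key(b, d, n_nodes)))
      continue;                            // would duplicate an edge
    retarget(e1, c);   // a->b  becomes  a->c
    retarget(e2, d);   // b->c  becomes  b->d
    retarget(e3, b);   // c->d  becomes  c->b
    swaps += 1;
  }
  PutRNGstate();

  return List::create(_["from"] = IntegerVector(efrom.begin(), efrom.end()),
                      _["to"] = IntegerVector(eto.begin(), eto.end()),
                      _["swaps"] = swaps, _["attempts"] = attempts);
}
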