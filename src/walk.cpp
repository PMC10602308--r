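#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>

using namespace Rcpp;

// Seeded self-avoiding (on edges) random walk over a signed directed network.
//
// Each walk starts at a uniformly chosen root and repeatedly steps along an
// untraversed outgoing edge chosen with probability proportional to
// (weight + eps). A walk stops when the last traversed edge is inhibitory,
// when the current node has no untraversed outgoing edge, or when max_length
// edges have been traversed. Chains are keyed by the dash-joined sequence of
// caller-supplied edge ids so that counts are comparable across networks
// sharing an edge-id space (the permutation null relies on this).
//
// Uses R's RNG (unif_rand) so results are reproducible via set.seed().
// [[Rcpp::export(name = ".walk_counts")]]
IntegerVector walk_counts(int n_nodes,
                          IntegerVector edge_from,   // 0-based node index
                          IntegerVector edge_to,     // 0-based node index
                          NumericVector edge_weight, // >= 0
                          LogicalVector edge_inhib,
                          IntegerVector edge_id,     // caller's edge identity
                          IntegerVector roots,       // 0-based node index
                          int n_walks,
                          int max_length,
                          double eps) {
  const int n_edges = edge_from.size();
  if (roots.size() == 0) stop("rootless network: no walk start points");
  if (n_walks < 1) stop("n_walks must be >= 1");
  if (eps < 0) stop("eps must be >= 0");

  std::vector< std::vector<int> > out(n_nodes);
  for (int e = 0; e < n_edges; ++e) out[edge_from[e]].push_back(e);

  std::vector<int> stamp(n_edges, -1);
  std::vector<int> chain;
  chain.reserve(max_length);
  std::unordered_map<std::string, int> counts;
  std::string key;

  RNGScope scope;
  const int n_roots = roots.size();

  for (int w = 0; w < n_walks; ++w) {
    int r = (int)(unif_rand() * n_roots);
    if (r >= n_roots) r = n_roots - 1;
    int cur = roots[r];
    chain.clear();

    while ((int)chain.size() < max_length) {
      // candidates: untraversed outgoing edges of cur
      double total = 0.0;
      const std::vector<int>& oe = out[cur];
      int n_cand = 0;
      for (size_t i = 0; i < oe.size(); ++i) {
        if (stamp[oe[i]] != w) {
          total += edge_weight[oe[i]] + eps;
          ++n_cand;
        }
      }
      if (n_cand == 0 || total <= 0.0) break; // sink
      double u = unif_rand() * total;
      int chosen = -1;
      double acc = 0.0;
      for (size_t i = 0; i < oe.size(); ++i) {
        if (stamp[oe[i]] != w) {
          acc += edge_weight[oe[i]] + eps;
          chosen = oe[i];
          if (u <= acc) break;
        }
      }
      stamp[chosen] = w;
      chain.push_back(chosen);
      cur = edge_to[chosen];
      if (edge_inhib[chosen]) break; // inhibition terminates the chain
    }

    key.clear();
    for (size_t i = 0; i < chain.size(); ++i) {
      if (i > 0) key.push_back('-');
      key += std::to_string(edge_id[chain[i]]);
    }
    counts[key] += 1;
  }

  IntegerVector res(counts.size());
  CharacterVector names(counts.size());
  int i = 0;
  for (std::unordered_map<std::string, int>::const_iterator it = counts.begin();
       it != counts.end(); ++it, ++i) {
    names[i] = it->first;
    res[i] = it->second;
  }
  res.attr("names") = names;
  return res;
}
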