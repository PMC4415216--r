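#include <Rcpp.h>
#include <unordered_set>
using namespace Rcpp;

static inline long long edge_key(int p, int g) {
  return (static_cast<long long>(p) << 32) | static_cast<unsigned int>(g);
}

// Degree-preserving randomization of a bipartite edge list by checked edge
// swaps: repeatedly pick two edges (p1,g1), (p2,g2) and replace them with
// (p1,g2), (p2,g1) unless either replacement already exists. Both the
// pathway and the gene degree sequences are preserved exactly. Uses R's RNG
// stream so set.seed() makes the walk reproducible.
// [[Rcpp::export]]
IntegerMatrix swap_bipartite_edges(IntegerVector pathway, IntegerVector gene,
                                   int n_swaps) {
  const int m = pathway.size();
  if (gene.size() != m) stop("pathway and gene index vectors differ in length");
  std::vector<int> pv(pathway.begin(), pathway.end());
  std::vector<int> gv(gene.begin(), gene.end());
  std::unordered_set<long long> edges;
  edges.reserve(2 * m);
  for (int e = 0; e < m; ++e) edges.insert(edge_key(pv[e], gv[e]));
  if ((int)edges.size() != m) stop("duplicate edges in bipartite edge list");
  if (m >= 2) {
    for (int s = 0; s < n_swaps; ++s) {
      int e1 = (int)(unif_rand() * m);
      int e2 = (int)(unif_rand() * m);
      if (e1 >= m) e1 = m - 1;
      if (e2 >= m) e2 = m - 1;
      if (e1 == e2) continue;
      const int p1 = pv[e1], g1 = gv[e1], p2 = pv[e2], g2 = gv[e2];
      if (p1 == p2 || g1 == g2) continue;
      const long long k1 = edge_key(p1, g2), k2 = edge_key(p2, g1);
      if (edges.count(k1) || edges.count(k2)) continue;
      edges.erase(edge_key(p1, g1));
      edges.erase(edge_key(p2, g2));
      edges.insert(k1);
      edges.insert(k2);
      gv[e1] = g2;
      gv[e2] = g1;
    }
  }
  IntegerMatrix out(m, 2);
  for (int e = 0; e < m; ++e) {
    out(e, 0) = pv[e];
    out(e, 1) = gv[e];
  }
  return out;
}
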