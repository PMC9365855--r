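#include <Rcpp.h>
using namespace Rcpp;

// Distance-binned degree-preserving double-edge swaps.
//
// edges: m x 2 matrix of 1-based endpoints (i < j); bin: length-m bin id
// per edge; dist_bin: n x n matrix of the bin id of every region pair;
// n_swaps: number of attempted swaps. A swap picks two distinct edges in
// the same bin, rewires (a,b)+(c,d) -> (a,d)+(c,b), and is accepted only
// when the new pairs are non-self, currently absent, and both fall in the
// same distance bin, so the degree sequence and per-bin edge counts are
// conserved exactly. Edge attributes (weights) travel with the rows of
// `edges`; the caller reassembles the matrix.
// [[Rcpp::export]]
IntegerMatrix rewire_swaps(IntegerMatrix edges, IntegerVector bin,
                           IntegerMatrix dist_bin, int n_swaps) {
  int m = edges.nrow();
  int n = dist_bin.nrow();
  IntegerMatrix out(clone(edges));
  // adjacency lookup
  std::vector<char> adj((size_t)n * n, 0);
  for (int e = 0; e < m; ++e) {
    int a = out(e, 0) - 1, b = out(e, 1) - 1;
    adj[(size_t)a * n + b] = 1;
    adj[(size_t)b * n + a] = 1;
  }
  // edges grouped by bin
  int max_bin = 0;
  for (int e = 0; e < m; ++e) if (bin[e] > max_bin) max_bin = bin[e];
  std::vector<std::vector<int>> by_bin(max_bin + 1);
  for (int e = 0; e < m; ++e) by_bin[bin[e]].push_back(e);
  // bins with >= 2 edges, sampled proportional to edge count
  std::vector<int> pool;
  for (int b = 0; b <= max_bin; ++b)
    if (by_bin[b].size() >= 2)
      for (size_t k = 0; k < by_bin[b].size(); ++k) pool.push_back(b);
  if (pool.empty()) return out;

  for (int s = 0; s < n_swaps; ++s) {
    int b = pool[(int)(unif_rand() * pool.size())];
    std::vector<int>& es = by_bin[b];
    int e1 = es[(int)(unif_rand() * es.size())];
    int e2 = es[(int)(unif_rand() * es.size())];
    if (e1 == e2) continue;
    int a = out(e1, 0) - 1, bb = out(e1, 1) - 1;
    int c = out(e2, 0) - 1, d = out(e2, 1) - 1;
    // randomly choose one of the two rewiring orientations
    if (unif_rand() < 0.5) { int t = c; c = d; d = t; }
    // proposed edges (a, d) and (c, bb)
    if (a == d || c == bb) continue;
    if (adj[(size_t)a * n + d] || adj[(size_t)c * n + bb]) continue;
    if (dist_bin(a, d) != b || dist_bin(c, bb) != b) continue;
    // accept
    adj[(size_t)a * n + bb] = 0; adj[(size_t)bb * n + a] = 0;
    adj[(size_t)c * n + d] = 0;  adj[(size_t)d * n + c] = 0;
    adj[(size_t)a * n + d] = 1;  adj[(size_t)d * n + a] = 1;
    adj[(size_t)c * n + bb] = 1; adj[(size_t)bb * n + c] = 1;
    out(e1, 0) = a + 1; out(e1, 1) = d + 1;
    out(e2, 0) = c + 1; out(e2, 1) = bb + 1;
  }
  return out;
}
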