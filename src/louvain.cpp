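#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Greedy ("Louvain-like") maximization of a quality function encoded in a
// dense symmetric modularity matrix B (diagonal null terms included).
// Q(partition) = sum_{ij : g_i == g_j} B_ij / twomu.
//
// Phase 1 sweeps node(-layer) tuples in a seeded random order, moving each
// tuple to the community with the largest strictly positive gain; phase 2
// aggregates communities into super-nodes (B' = S^T B S) and repeats.
// Deterministic for a given seed.

static double partition_quality(const std::vector<double> &B, int n,
                                const std::vector<int> &lab) {
  double q = 0.0;
  for (int i = 0; i < n; ++i) {
    const double *col = &B[(size_t)i * n];
    int li = lab[i];
    for (int j = 0; j < n; ++j) {
      if (lab[j] == li) q += col[j];
    }
  }
  return q;
}

// One full local-move + aggregation cycle on matrix B; returns labels on
// the current node set. `moved_any` reports whether any move happened.
static std::vector<int> local_moves(const std::vector<double> &B, int n,
                                    std::mt19937 &rng, bool &moved_any) {
  std::vector<int> lab(n);
  for (int i = 0; i < n; ++i) lab[i] = i;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::vector<double> conn(n);
  moved_any = false;
  bool moved = true;
  while (moved) {
    moved = false;
    std::shuffle(order.begin(), order.end(), rng);
    for (int oi = 0; oi < n; ++oi) {
      int v = order[oi];
      int cur = lab[v];
      std::fill(conn.begin(), conn.end(), 0.0);
      const double *col = &B[(size_t)v * n];
      for (int u = 0; u < n; ++u) conn[lab[u]] += col[u];
      conn[cur] -= col[v];           // exclude the self term
      double cur_gain = conn[cur];
      int best = cur;
      double best_gain = cur_gain;
      for (int c = 0; c < n; ++c) {
        if (conn[c] > best_gain + 1e-12 * (std::fabs(best_gain) + 1.0)) {
          best_gain = conn[c];
          best = c;
        }
      }
      if (best != cur) {
        lab[v] = best;
        moved = true;
        moved_any = true;
      }
    }
  }
  return lab;
}

// [[Rcpp::export]]
List louvain_dense(NumericMatrix Bmat, double twomu, int seed) {
  int n = Bmat.nrow();
  if (Bmat.ncol() != n) stop("B must be square");
  std::vector<double> B(Bmat.begin(), Bmat.end());
  std::vector<int> glob(n);
  for (int i = 0; i < n; ++i) glob[i] = i;
  std::mt19937 rng((unsigned)seed);

  int nc = n;
  while (true) {
    bool moved_any = false;
    std::vector<int> lab = local_moves(B, nc, rng, moved_any);
    // compact labels
    std::vector<int> remap(nc, -1);
    int k = 0;
    for (int i = 0; i < nc; ++i) {
      if (remap[lab[i]] < 0) remap[lab[i]] = k++;
    }
    for (int i = 0; i < nc; ++i) lab[i] = remap[lab[i]];
    for (int i = 0; i < n; ++i) glob[i] = lab[glob[i]];
    if (!moved_any || k == nc) break;
    // aggregate: B' = S^T B S
    std::vector<double> Bn((size_t)k * k, 0.0);
    for (int i = 0; i < nc; ++i) {
      const double *col = &B[(size_t)i * nc];
      int li = lab[i];
      for (int j = 0; j < nc; ++j) {
        Bn[(size_t)li * k + lab[j]] += col[j];
      }
    }
    B.swap(Bn);
    nc = k;
  }

  // quality on the original matrix
  std::vector<double> Borig(Bmat.begin(), Bmat.end());
  double q = partition_quality(Borig, n, glob) / twomu;

  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = glob[i] + 1;
  return List::create(_["labels"] = out, _["Q"] = q);
}
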