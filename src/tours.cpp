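#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Randomized nearest-neighbour tour construction replicated across a bank
// of modules. All randomness arrives pre-drawn in `draws` (one row per
// module, one uniform in [0,1) per destination decision), so the kernel is
// a pure function of its arguments.
//
// d:      L x L symmetric distance matrix
// start:  1-based start index
// nbr:    L x (L-1) matrix; row i = the other locations sorted ascending
//         by distance from i, ties by lower index (1-based)
// mode:   0 deterministic-nn, 1 position-weighted, 2 value-weighted
// weight: exponent for mode 1; weight >= 10 degenerates to mode 0
// draws:  n_modules x (L-1)
//
// Returns per-module totals, the best module's row index (1-based, ties to
// the lowest index) and its visit order (1-based location indices).
// [[Rcpp::export]]
List tour_kernel(NumericMatrix d, int start, IntegerMatrix nbr,
                 int mode, double weight, NumericMatrix draws) {
  const int L = d.nrow();
  const int n_dest = L - 1;
  const int n_mod = draws.nrow();
  if (mode == 1 && weight >= 10.0) mode = 0;

  // Position-weighted cumulative weights per candidate-count m:
  // cum[m][j] = sum_{k=1..j+1} (m - k + 1)^weight, j = 0..m-1.
  std::vector< std::vector<double> > cum(n_dest + 1);
  if (mode == 1) {
    for (int m = 1; m <= n_dest; ++m) {
      cum[m].resize(m);
      double s = 0.0;
      for (int k = 1; k <= m; ++k) {
        s += std::pow((double)(m - k + 1), weight);
        cum[m][k - 1] = s;
      }
    }
  }

  NumericVector totals(n_mod);
  IntegerVector best_order(n_dest);
  double best_total = R_PosInf;
  int best_index = NA_INTEGER;
  std::vector<char> visited(L);
  std::vector<int> cand(n_dest);
  std::vector<double> cdist(n_dest), vcum(n_dest);
  std::vector<int> order(n_dest);
  const int s0 = start - 1;

  for (int mod = 0; mod < n_mod; ++mod) {
    std::fill(visited.begin(), visited.end(), 0);
    visited[s0] = 1;
    int cur = s0;
    double tot = 0.0;
    for (int step = 0; step < n_dest; ++step) {
      int m = 0;
      for (int k = 0; k < n_dest; ++k) {
        int j = nbr(cur, k) - 1;
        if (!visited[j]) {
          cand[m] = j;
          cdist[m] = d(cur, j);
          ++m;
        }
      }
      int pick = 0;
      if (mode == 1 && m > 1) {
        const std::vector<double>& cw = cum[m];
        const double target = draws(mod, step) * cw[m - 1];
        while (pick < m - 1 && cw[pick] <= target) ++pick;
      } else if (mode == 2 && m > 1) {
        double s = 0.0;
        for (int j = 0; j < m; ++j) {
          double diff = cdist[j] - cdist[0];
          s += 1.0 / (diff > 1.0 ? diff : 1.0);
          vcum[j] = s;
        }
        const double target = draws(mod, step) * s;
        while (pick < m - 1 && vcum[pick] <= target) ++pick;
      }
      const int nxt = cand[pick];
      visited[nxt] = 1;
      tot += cdist[pick];
      order[step] = nxt;
      cur = nxt;
    }
    tot += d(cur, s0);
    totals[mod] = tot;
    if (tot < best_total) {
      best_total = tot;
      best_index = mod + 1;
      for (int k = 0; k < n_dest; ++k) best_order[k] = order[k] + 1;
    }
  }
  return List::create(_["totals"] = totals,
                      _["best_total"] = best_total,
                      _["best_index"] = best_index,
                      _["best_order"] = best_order);
}
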