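#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Greedy Zonation-style cell removal.
//
// Q:        F x N matrix of per-cell feature proportions over analysis cells
//           (columns ordered by row-major linear cell index).
// cost:     length-N positive cell costs.
// level:    length-N non-negative removal-mask levels; all cells of level k
//           are removed before any cell of level k+1.
// z:        exponent of the additive benefit function.
// warp:     cells removed per marginal-loss evaluation (1 = exact greedy).
// objective: 0 = ABF (additive benefit), 1 = CAZ (core-area, max ratio).
// trajectory: record q_jn after every single removal (performance curves).
//
// Ties in marginal loss are broken by lowest cell index. q_jn is maintained
// incrementally and recomputed from scratch every 1000 removals to bound
// floating-point drift.
// [[Rcpp::export(name = ".greedy_rank_cpp")]]
List greedy_rank_cpp(NumericMatrix Q, NumericVector qjn0, NumericVector cost,
                     IntegerVector level, double z, int warp, int objective,
                     bool trajectory) {
  const int F = Q.nrow(), N = Q.ncol();
  if (cost.size() != N || level.size() != N)
    stop("cost/level length does not match the number of analysis cells");
  if (qjn0.size() != F)
    stop("qjn0 length does not match the number of features");

  // column-sparse view of Q: features present in each cell
  std::vector<std::vector<int>> nz_f(N);
  std::vector<std::vector<double>> nz_q(N);
  for (int i = 0; i < N; ++i) {
    for (int j = 0; j < F; ++j) {
      double v = Q(j, i);
      if (v != 0.0) { nz_f[i].push_back(j); nz_q[i].push_back(v); }
    }
  }

  // starting totals are computed on the R side so that this core and the
  // naive reference implementation share bit-identical initial state
  std::vector<double> qjn(qjn0.begin(), qjn0.end());

  std::vector<bool> removed(N, false);
  IntegerVector order_out(N);
  NumericMatrix traj = trajectory ? NumericMatrix(N, F) : NumericMatrix(0, 0);

  std::vector<int> levels_sorted(level.begin(), level.end());
  std::sort(levels_sorted.begin(), levels_sorted.end());
  levels_sorted.erase(std::unique(levels_sorted.begin(), levels_sorted.end()),
                      levels_sorted.end());

  std::vector<double> qz(F, 0.0);
  std::vector<double> delta;
  std::vector<int> cells;
  int n_removed = 0, since_recompute = 0;

  for (int lv : levels_sorted) {
    // active cells of this mask level, ascending index (stable tie-break)
    cells.clear();
    for (int i = 0; i < N; ++i) if (level[i] == lv) cells.push_back(i);

    while (!cells.empty()) {
      if (objective == 0)
        for (int j = 0; j < F; ++j) qz[j] = std::pow(std::max(qjn[j], 0.0), z);

      delta.assign(cells.size(), 0.0);
      for (size_t k = 0; k < cells.size(); ++k) {
        int i = cells[k];
        const std::vector<int>& fj = nz_f[i];
        const std::vector<double>& fq = nz_q[i];
        double d = 0.0;
        if (objective == 0) { // ABF
          for (size_t t = 0; t < fj.size(); ++t) {
            int j = fj[t];
            double rem = qjn[j] - fq[t];
            if (rem < -1e-9)
              stop("state corruption: q_jn - q_ji < -1e-9 for a feature");
            if (rem < 0.0) rem = 0.0;
            d += qz[j] - std::pow(rem, z);
          }
        } else { // CAZ
          for (size_t t = 0; t < fj.size(); ++t) {
            int j = fj[t];
            if (qjn[j] > 0.0) {
              double r = fq[t] / qjn[j];
              if (r > d) d = r;
            }
          }
        }
        delta[k] = d / cost[i];
      }

      // pick the `warp` smallest-delta cells; ties by lowest cell index
      int take = std::min<int>(warp, (int)cells.size());
      std::vector<int> sel(cells.size());
      for (size_t k = 0; k < cells.size(); ++k) sel[k] = (int)k;
      std::partial_sort(sel.begin(), sel.begin() + take, sel.end(),
                        [&](int a, int b) {
                          if (delta[a] != delta[b]) return delta[a] < delta[b];
                          return cells[a] < cells[b];
                        });
      sel.resize(take);
      // remove in delta order (then index order) within the batch
      for (int k : sel) {
        int i = cells[k];
        removed[i] = true;
        const std::vector<int>& fj = nz_f[i];
        const std::vector<double>& fq = nz_q[i];
        for (size_t t = 0; t < fj.size(); ++t) {
          qjn[fj[t]] -= fq[t];
          if (qjn[fj[t]] < 0.0) qjn[fj[t]] = 0.0;
        }
        order_out[n_removed] = i + 1; // 1-based for R
        if (trajectory)
          for (int j = 0; j < F; ++j) traj(n_removed, j) = qjn[j];
        ++n_removed;
        if (++since_recompute >= 1000) {
          for (int j = 0; j < F; ++j) {
            long double s = 0.0;
            for (int i2 = 0; i2 < N; ++i2) if (!removed[i2]) s += Q(j, i2);
            qjn[j] = (double)s;
          }
          since_recompute = 0;
        }
      }
      // drop removed cells from the active list, preserving index order
      std::vector<int> keep;
      keep.reserve(cells.size() - take);
      for (int i : cells) if (!removed[i]) keep.push_back(i);
      cells.swap(keep);
    }
  }

  return List::create(_["order"] = order_out, _["trajectory"] = traj);
}
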