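// Regression forest with per-split event recording.
//
// Each tree is a CART regression tree grown on a bootstrap sample (size n,
// with replacement), choosing at each node `mtry` candidate predictors and the
// split maximizing the reduction in residual sum of squares. Every accepted
// split is recorded as (predictor, threshold, SSE reduction); reductions are
// also accumulated per predictor and into fixed bins over each predictor's
// observed range, so forests over many loci can be aggregated without keeping
// every split event in memory. Out-of-bag predictions are accumulated per
// sample for the OOB R^2.
//
// Split search uses presorted predictors: each column is argsorted once per
// call; per tree the bootstrap multiset is expanded in sorted order for every
// predictor, and node partitions are stable partitions of those index arrays,
// so no per-node sorting is needed.
//
// Randomness comes from a std::mt19937 seeded explicitly, so fits are
// reproducible across platforms independent of R's RNG state.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <numeric>
#include <random>
#include <cstdint>

using namespace Rcpp;

namespace {

struct TreeNode {
  int var;       // -1 for leaf
  double thr;
  int left, right;
  double value;  // node mean (prediction if leaf)
};

struct BuildTask {
  int node_id;
  int start, end;       // range shared by all per-predictor index arrays
  double sum, sumsq;    // response moments over the range
};

inline double node_sse(double sum, double sumsq, int n) {
  double sse = sumsq - sum * sum / n;
  return sse > 0.0 ? sse : 0.0;
}

}  // namespace

// [[Rcpp::export(name = ".fit_forest_cpp")]]
List fit_forest_cpp(NumericMatrix X, NumericVector y,
                    int n_trees, int mtry, int min_node, int seed,
                    NumericVector bin_lo, NumericVector bin_hi, int n_bins,
                    bool return_splits) {
  const int n = X.nrow();
  const int p = X.ncol();
  if (n < 2) stop("need at least 2 samples");
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  if (min_node < 1) min_node = 1;

  const double *xp = REAL(X);
  const double *yp = REAL(y);

  std::mt19937 rng(static_cast<std::uint32_t>(seed));
  std::uniform_int_distribution<int> pick(0, n - 1);

  std::vector<double> oob_sum(n, 0.0);
  std::vector<int> oob_cnt(n, 0);
  std::vector<double> imp(p, 0.0);
  NumericMatrix bin_imp(p, n_bins);
  std::fill(bin_imp.begin(), bin_imp.end(), 0.0);

  std::vector<int> sp_var;
  std::vector<double> sp_thr, sp_red;

  // global argsort of each predictor (ties keep index order)
  std::vector<int> gorder(static_cast<size_t>(p) * n);
  for (int v = 0; v < p; ++v) {
    int *ord = gorder.data() + static_cast<size_t>(v) * n;
    std::iota(ord, ord + n, 0);
    const double *col = xp + static_cast<size_t>(v) * n;
    std::stable_sort(ord, ord + n,
                     [col](int a, int b) { return col[a] < col[b]; });
  }

  std::vector<int> inbag(n);
  std::vector<int> sorted(static_cast<size_t>(p) * n);  // per-tree, per-var
  std::vector<int> buf(n);                              // partition scratch
  std::vector<int> vars(p);
  std::vector<char> goes_left(n);

  for (int t = 0; t < n_trees; ++t) {
    // bootstrap counts
    std::fill(inbag.begin(), inbag.end(), 0);
    for (int i = 0; i < n; ++i) inbag[pick(rng)]++;

    // expand the bootstrap multiset in presorted order for every predictor
    int B = 0;
    for (int v = 0; v < p; ++v) {
      const int *ord = gorder.data() + static_cast<size_t>(v) * n;
      int *dst = sorted.data() + static_cast<size_t>(v) * n;
      int k = 0;
      for (int j = 0; j < n; ++j) {
        const int i = ord[j];
        for (int r = 0; r < inbag[i]; ++r) dst[k++] = i;
      }
      B = k;
    }

    std::vector<TreeNode> nodes;
    nodes.reserve(64);
    double s0 = 0.0, ss0 = 0.0;
    {
      const int *a = sorted.data();  // any predictor order covers the multiset
      for (int k = 0; k < B; ++k) {
        const double v = yp[a[k]];
        s0 += v;
        ss0 += v * v;
      }
    }
    nodes.push_back(TreeNode{-1, 0.0, -1, -1, s0 / B});

    std::vector<BuildTask> stack;
    stack.push_back(BuildTask{0, 0, B, s0, ss0});

    while (!stack.empty()) {
      BuildTask task = stack.back();
      stack.pop_back();
      const int m = task.end - task.start;
      const double parent_sse = node_sse(task.sum, task.sumsq, m);
      if (m < 2 * min_node || parent_sse <= 1e-12) continue;  // leaf

      // draw mtry candidate predictors (partial Fisher-Yates)
      for (int v = 0; v < p; ++v) vars[v] = v;
      for (int v = 0; v < mtry; ++v) {
        std::uniform_int_distribution<int> dv(v, p - 1);
        std::swap(vars[v], vars[dv(rng)]);
      }

      int best_var = -1;
      double best_red = 1e-12, best_thr = 0.0;
      for (int vi = 0; vi < mtry; ++vi) {
        const int v = vars[vi];
        const double *col = xp + static_cast<size_t>(v) * n;
        const int *a = sorted.data() + static_cast<size_t>(v) * n;
        double lsum = 0.0, lss = 0.0;
        for (int i = 1; i < m; ++i) {
          const double yv = yp[a[task.start + i - 1]];
          lsum += yv;
          lss += yv * yv;
          const double xl = col[a[task.start + i - 1]];
          const double xr = col[a[task.start + i]];
          if (xr <= xl) continue;                          // tied values
          if (i < min_node || m - i < min_node) continue;  // child size
          const double red = parent_sse - node_sse(lsum, lss, i) -
                             node_sse(task.sum - lsum, task.sumsq - lss, m - i);
          if (red > best_red) {
            best_red = red;
            best_var = v;
            best_thr = 0.5 * (xl + xr);
          }
        }
      }
      if (best_var < 0) continue;  // no admissible split

      // membership of the chosen split, then stable-partition every
      // predictor's index range so children stay presorted
      const double *bcol = xp + static_cast<size_t>(best_var) * n;
      int nl = 0;
      {
        const int *a = sorted.data() + static_cast<size_t>(best_var) * n;
        for (int k = task.start; k < task.end; ++k) {
          const bool l = bcol[a[k]] <= best_thr;
          goes_left[a[k]] = l;  // per-sample flag (repeats share the flag)
          if (l) ++nl;
        }
      }
      const int nr = m - nl;
      if (nl == 0 || nr == 0) continue;  // numerically degenerate; leaf

      double lsum = 0.0, lss = 0.0;
      for (int v = 0; v < p; ++v) {
        int *a = sorted.data() + static_cast<size_t>(v) * n;
        int kl = task.start, kr = 0;
        for (int k = task.start; k < task.end; ++k) {
          const int i = a[k];
          if (goes_left[i]) {
            if (v == 0) {
              const double yv = yp[i];
              lsum += yv;
              lss += yv * yv;
            }
            a[kl++] = i;
          } else {
            buf[kr++] = i;
          }
        }
        std::copy(buf.begin(), buf.begin() + kr, a + kl);
      }

      imp[best_var] += best_red;
      const double span = bin_hi[best_var] - bin_lo[best_var];
      int b = span > 0.0
                  ? static_cast<int>((best_thr - bin_lo[best_var]) / span * n_bins)
                  : 0;
      if (b < 0) b = 0;
      if (b >= n_bins) b = n_bins - 1;
      bin_imp(best_var, b) += best_red;
      if (return_splits) {
        sp_var.push_back(best_var);
        sp_thr.push_back(best_thr);
        sp_red.push_back(best_red);
      }

      TreeNode &nd = nodes[task.node_id];
      nd.var = best_var;
      nd.thr = best_thr;
      nd.left = static_cast<int>(nodes.size());
      nd.right = nd.left + 1;
      nodes.push_back(TreeNode{-1, 0.0, -1, -1, lsum / nl});
      nodes.push_back(TreeNode{-1, 0.0, -1, -1, (task.sum - lsum) / nr});
      stack.push_back(BuildTask{nd.left, task.start, task.start + nl, lsum, lss});
      stack.push_back(BuildTask{nd.right, task.start + nl, task.end,
                                task.sum - lsum, task.sumsq - lss});
    }

    // OOB predictions
    for (int i = 0; i < n; ++i) {
      if (inbag[i] > 0) continue;
      int node = 0;
      while (nodes[node].var >= 0) {
        const TreeNode &nd = nodes[node];
        node = xp[static_cast<size_t>(nd.var) * n + i] <= nd.thr ? nd.left
                                                                 : nd.right;
      }
      oob_sum[i] += nodes[node].value;
      oob_cnt[i]++;
    }
  }

  NumericVector oob_pred(n, NA_REAL);
  int n_oob = 0;
  for (int i = 0; i < n; ++i) {
    if (oob_cnt[i] > 0) {
      oob_pred[i] = oob_sum[i] / oob_cnt[i];
      ++n_oob;
    }
  }

  List out = List::create(
      _["oob_pred"] = oob_pred, _["n_oob"] = n_oob,
      _["importance"] = NumericVector(imp.begin(), imp.end()),
      _["bin_importance"] = bin_imp);
  if (return_splits) {
    out["splits"] = DataFrame::create(
        _["var"] = IntegerVector(sp_var.begin(), sp_var.end()),
        _["value"] = NumericVector(sp_thr.begin(), sp_thr.end()),
        _["improvement"] = NumericVector(sp_red.begin(), sp_red.end()));
  }
  return out;
}
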