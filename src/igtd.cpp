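#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// per-pair error term: absolute rank difference, or its square
static inline double pe(double a, double b, bool squared) {
  double d = std::fabs(a - b);
  return squared ? d * d : d;
}

// total rank-matching error: sum over pairs i<j of the per-pair term on
// feature_rank[order[i], order[j]] vs pixel_rank[i, j]
// [[Rcpp::export]]
double igtd_error_cpp(NumericMatrix fr, NumericMatrix pr, IntegerVector order,
                      bool squared = false) {
  int n = pr.nrow();
  if (fr.nrow() != n || fr.ncol() != n || pr.ncol() != n)
    stop("rank matrices must be square and of equal size");
  if (order.size() != n) stop("order length must match matrix size");
  double e = 0.0;
  for (int i = 0; i < n; ++i) {
    int oi = order[i] - 1;
    for (int j = i + 1; j < n; ++j) {
      e += pe(fr(oi, order[j] - 1), pr(i, j), squared);
    }
  }
  return e;
}

// Iterative swap optimisation of the feature->pixel assignment.
// Each outer iteration picks the grid cell with the largest error
// contribution among cells not examined within the last `lookback`
// iterations, evaluates swapping its feature with every other cell's
// feature, and applies the best strictly-improving swap. Ties are broken by
// the lowest cell index, so the routine is fully deterministic.
// On instances of up to `cycle3_max` cells, once the pairwise-swap
// neighbourhood is exhausted a strictly-improving 3-cycle is sought, which
// lets small instances escape 2-swap local optima while keeping the error
// trajectory non-increasing. patience = 0 disables early stopping.
// [[Rcpp::export]]
List igtd_optimize_cpp(NumericMatrix fr, NumericMatrix pr, int n_iterations,
                       int lookback, int patience, int cycle3_max = 64,
                       Nullable<IntegerVector> init_order = R_NilValue,
                       bool squared = false) {
  int n = pr.nrow();
  if (fr.nrow() != n || fr.ncol() != n || pr.ncol() != n)
    stop("rank matrices must be square and of equal size");
  if (n < 2) stop("need at least 2 features");
  if (n_iterations < 1) stop("'n_iterations' must be >= 1");

  std::vector<int> order(n);          // cell index -> feature index (0-based)
  if (init_order.isNotNull()) {
    IntegerVector io(init_order);
    if (io.size() != n) stop("init_order length must match matrix size");
    for (int i = 0; i < n; ++i) order[i] = io[i] - 1;
  } else {
    for (int i = 0; i < n; ++i) order[i] = i;
  }

  // per-cell error contributions and total error
  std::vector<double> contrib(n, 0.0);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    double c = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      c += pe(fr(order[i], order[j]), pr(i, j), squared);
    }
    contrib[i] = c;
    total += c;
  }
  total /= 2.0;

  std::vector<int> last_exam(n, -1000000000);
  NumericVector trajectory(n_iterations + 1);
  trajectory[0] = total;
  int since_improved = 0;
  bool cycle3_done = false;
  int done = n_iterations;

  for (int t = 1; t <= n_iterations; ++t) {
    // base cell: max contribution among those outside the lookback window
    int base = -1;
    double best_c = -1.0;
    for (int i = 0; i < n; ++i) {
      if (t - last_exam[i] <= lookback) continue;
      if (contrib[i] > best_c) { best_c = contrib[i]; base = i; }
    }
    if (base < 0) {                   // all recently examined: plain argmax
      for (int i = 0; i < n; ++i)
        if (contrib[i] > best_c) { best_c = contrib[i]; base = i; }
    }
    last_exam[base] = t;

    // best strictly-improving swap partner for `base`
    int best_k = -1;
    double best_delta = 0.0;
    int ob = order[base];
    for (int k = 0; k < n; ++k) {
      if (k == base) continue;
      int ok = order[k];
      double delta = 0.0;
      for (int j = 0; j < n; ++j) {
        if (j == base || j == k) continue;
        int oj = order[j];
        delta += pe(fr(ok, oj), pr(base, j), squared)
               - pe(fr(ob, oj), pr(base, j), squared)
               + pe(fr(ob, oj), pr(k, j), squared)
               - pe(fr(ok, oj), pr(k, j), squared);
      }
      if (delta < best_delta - 1e-12) { best_delta = delta; best_k = k; }
    }

    if (best_k >= 0) {
      int k = best_k, ok = order[k];
      // update contributions incrementally
      double cb = 0.0, ck = 0.0;
      for (int j = 0; j < n; ++j) {
        if (j == base || j == k) continue;
        int oj = order[j];
        double old_bj = pe(fr(ob, oj), pr(base, j), squared);
        double new_bj = pe(fr(ok, oj), pr(base, j), squared);
        double old_kj = pe(fr(ok, oj), pr(k, j), squared);
        double new_kj = pe(fr(ob, oj), pr(k, j), squared);
        contrib[j] += (new_bj - old_bj) + (new_kj - old_kj);
        cb += new_bj;
        ck += new_kj;
      }
      double cross = pe(fr(ob, ok), pr(base, k), squared);
      contrib[base] = cb + cross;
      contrib[k] = ck + cross;
      order[base] = ok;
      order[k] = ob;
      total += best_delta;
      if (total < 0 && total > -1e-9) total = 0.0;
      since_improved = 0;
      cycle3_done = false;
    } else {
      ++since_improved;
    }

    // 2-swap neighbourhood exhausted on a small instance: look for a
    // strictly-improving 3-cycle (both rotation directions)
    if (best_k < 0 && n <= cycle3_max && since_improved >= n && !cycle3_done) {
      double best_d3 = -1e-12;
      int bi = -1, bj = -1, bk = -1, bdir = 0;
      std::vector<int> trial(order);
      for (int i = 0; i < n - 2; ++i)
        for (int j = i + 1; j < n - 1; ++j)
          for (int k = j + 1; k < n; ++k)
            for (int dir = 0; dir < 2; ++dir) {
              trial[i] = order[dir ? j : k];
              trial[j] = order[dir ? k : i];
              trial[k] = order[dir ? i : j];
              // error delta restricted to rows i, j, k
              double d = 0.0;
              int moved[3] = {i, j, k};
              for (int mi = 0; mi < 3; ++mi) {
                int r = moved[mi];
                for (int c = 0; c < n; ++c) {
                  if (c == r) continue;
                  bool c_moved = (c == i || c == j || c == k);
                  if (c_moved && c < r) continue;   // count moved pairs once
                  d += pe(fr(trial[r], trial[c]), pr(r, c), squared)
                     - pe(fr(order[r], order[c]), pr(r, c), squared);
                }
              }
              if (d < best_d3) { best_d3 = d; bi = i; bj = j; bk = k; bdir = dir; }
              trial[i] = order[i]; trial[j] = order[j]; trial[k] = order[k];
            }
      if (bi >= 0) {
        int oi = order[bi], oj = order[bj], ok2 = order[bk];
        order[bi] = bdir ? oj : ok2;
        order[bj] = bdir ? ok2 : oi;
        order[bk] = bdir ? oi : oj;
        total += best_d3;
        for (int i2 = 0; i2 < n; ++i2) {       // refresh contributions
          double c2 = 0.0;
          for (int j2 = 0; j2 < n; ++j2) {
            if (j2 == i2) continue;
            c2 += pe(fr(order[i2], order[j2]), pr(i2, j2), squared);
          }
          contrib[i2] = c2;
        }
        since_improved = 0;
      } else {
        cycle3_done = true;                    // fully converged
      }
    }

    trajectory[t] = total;
    if (patience > 0 && since_improved >= patience) { done = t; break; }
  }

  IntegerVector ord(n);
  for (int i = 0; i < n; ++i) ord[i] = order[i] + 1;
  return List::create(_["order"] = ord,
                      _["trajectory"] = trajectory[Range(0, done)],
                      _["iterations_run"] = done);
}
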