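#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Dual coordinate descent for the L1-loss (hinge) linear SVM, following the
// LIBLINEAR algorithm (Hsieh et al., ICML 2008), including its shrinking
// heuristic and its stopping rule (projected-gradient spread < eps). The
// bias is an appended constant feature of value `bias_scale`, so it is part
// of the regularized weight vector, as in LIBLINEAR. Per-instance upper
// bounds Ci allow exact collapsing of duplicated training rows: m identical
// points at cost C are equivalent to one point at cost m*C because hinge
// slacks of identical points add.
//
// The feature matrix arrives in compressed sparse row form (0-based column
// indices); binary edge-indicator features are mostly zeros, and the sparse
// dot products dominate the run time.
// [[Rcpp::export]]
List dcd_svm_fit(IntegerVector row_ptr, IntegerVector col_idx,
                 NumericVector val, int n, int d, IntegerVector y,
                 NumericVector Ci, double eps, int max_epochs,
                 double bias_scale, int shuffle_seed) {
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> w(d + 1, 0.0);
  std::vector<double> alpha(n, 0.0);
  std::vector<double> qii(n);
  const double b2 = bias_scale * bias_scale;

  for (int i = 0; i < n; ++i) {
    double s = b2;
    for (int p = row_ptr[i]; p < row_ptr[i + 1]; ++p) s += val[p] * val[p];
    qii[i] = s;
  }

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  // deterministic xorshift shuffling, independent of R's RNG state
  unsigned int rng = (unsigned int)shuffle_seed;
  if (rng == 0u) rng = 88172645u;
  auto next_rand = [&rng]() {
    rng ^= rng << 13;
    rng ^= rng >> 17;
    rng ^= rng << 5;
    return rng;
  };

  int active = n;
  double pgmax_old = inf, pgmin_old = -inf;
  int epoch = 0;
  bool converged = false;

  for (; epoch < max_epochs; ++epoch) {
    double pgmax_new = -inf, pgmin_new = inf;
    for (int i = active - 1; i > 0; --i) {
      int j = (int)(next_rand() % (unsigned int)(i + 1));
      std::swap(order[i], order[j]);
    }
    for (int t = 0; t < active; ++t) {
      const int i = order[t];
      double f = w[d] * bias_scale;
      for (int p = row_ptr[i]; p < row_ptr[i + 1]; ++p) {
        f += w[col_idx[p]] * val[p];
      }
      const double G = y[i] * f - 1.0;
      double pg = G;
      if (alpha[i] <= 0.0) {
        if (G > pgmax_old) {  // shrink: inactive at the lower bound
          std::swap(order[t], order[active - 1]);
          --active;
          --t;
          continue;
        }
        if (G >= 0.0) pg = 0.0;
      } else if (alpha[i] >= Ci[i]) {
        if (G < pgmin_old) {  // shrink: inactive at the upper bound
          std::swap(order[t], order[active - 1]);
          --active;
          --t;
          continue;
        }
        if (G <= 0.0) pg = 0.0;
      }
      if (pg > pgmax_new) pgmax_new = pg;
      if (pg < pgmin_new) pgmin_new = pg;
      if (std::fabs(pg) > 1e-14) {
        double a_new = alpha[i] - G / qii[i];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > Ci[i]) a_new = Ci[i];
        const double delta = (a_new - alpha[i]) * y[i];
        if (delta != 0.0) {
          alpha[i] = a_new;
          for (int p = row_ptr[i]; p < row_ptr[i + 1]; ++p) {
            w[col_idx[p]] += delta * val[p];
          }
          w[d] += delta * bias_scale;
        }
      }
    }
    if (pgmax_new - pgmin_new <= eps) {
      if (active == n) {
        converged = true;
        ++epoch;
        break;
      }
      // optimum reached on the shrunk set: re-activate everything and
      // confirm with untightened bounds
      active = n;
      pgmax_old = inf;
      pgmin_old = -inf;
      continue;
    }
    pgmax_old = (pgmax_new <= 0.0) ? inf : pgmax_new;
    pgmin_old = (pgmin_new >= 0.0) ? -inf : pgmin_new;
  }

  NumericVector w_out(d);
  for (int j = 0; j < d; ++j) w_out[j] = w[j];
  return List::create(
    _["w"] = w_out,
    _["b"] = w[d] * bias_scale,
    _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
    _["epochs"] = epoch,
    _["converged"] = converged
  );
}
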