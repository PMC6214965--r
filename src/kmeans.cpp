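#include <Rcpp.h>
using namespace Rcpp;

// Squared Euclidean distance between row i of X and center row c of C.
static inline double row_center_d2(const NumericMatrix &X, int i,
                                   const NumericMatrix &C, int c) {
  const int d = X.ncol();
  double s = 0.0;
  for (int j = 0; j < d; ++j) {
    const double diff = X(i, j) - C(c, j);
    s += diff * diff;
  }
  return s;
}

// One full Lloyd run from given initial centers. Writes final labels
// (0-based), centers and SSE trace; returns final SSE. Empty clusters are
// re-seeded at the point currently farthest from its own center.
static double lloyd_run(const NumericMatrix &X, NumericMatrix &C,
                        IntegerVector &labels, int max_iter, double tol,
                        std::vector<double> *trace) {
  const int n = X.nrow(), d = X.ncol(), k = C.nrow();
  std::vector<int> counts(k);
  double prev_sse = R_PosInf, sse = R_PosInf;
  bool changed = true;

  for (int it = 0; it < max_iter && changed; ++it) {
    // assignment step
    changed = false;
    sse = 0.0;
    for (int i = 0; i < n; ++i) {
      int best = 0;
      double bestd = row_center_d2(X, i, C, 0);
      for (int c = 1; c < k; ++c) {
        const double dd = row_center_d2(X, i, C, c);
        if (dd < bestd) { bestd = dd; best = c; }
      }
      if (labels[i] != best) { labels[i] = best; changed = true; }
      sse += bestd;
    }
    // SSE is non-increasing along Lloyd iterations; guard numerically
    if (sse > prev_sse + 1e-9 * (1.0 + prev_sse))
      stop("internal error: SSE increased during Lloyd iteration");
    if (trace) trace->push_back(sse);
    const bool converged = !changed ||
      (R_finite(prev_sse) && prev_sse - sse < tol);
    prev_sse = sse;
    if (converged) break;

    // update step
    std::fill(counts.begin(), counts.end(), 0);
    std::fill(C.begin(), C.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      counts[labels[i]]++;
      for (int j = 0; j < d; ++j) C(labels[i], j) += X(i, j);
    }
    for (int c = 0; c < k; ++c) {
      if (counts[c] > 0) {
        for (int j = 0; j < d; ++j) C(c, j) /= counts[c];
      } else {
        // re-seed an empty cluster at the worst-fitted point
        int far_i = 0; double far_d = -1.0;
        for (int i = 0; i < n; ++i) {
          const double dd = row_center_d2(X, i, C, labels[i]);
          if (dd > far_d) { far_d = dd; far_i = i; }
        }
        for (int j = 0; j < d; ++j) C(c, j) = X(far_i, j);
        changed = true;
      }
    }
  }

  // make centers exactly the means of their final members
  std::fill(counts.begin(), counts.end(), 0);
  NumericMatrix M(k, d);
  for (int i = 0; i < n; ++i) {
    counts[labels[i]]++;
    for (int j = 0; j < d; ++j) M(labels[i], j) += X(i, j);
  }
  for (int c = 0; c < k; ++c)
    if (counts[c] > 0)
      for (int j = 0; j < d; ++j) C(c, j) = M(c, j) / counts[c];
  sse = 0.0;
  for (int i = 0; i < n; ++i) sse += row_center_d2(X, i, C, labels[i]);
  return sse;
}

// k-means++ seeding using R's RNG (reproducible under set.seed()).
static void kmeanspp_init(const NumericMatrix &X, NumericMatrix &C) {
  const int n = X.nrow(), d = X.ncol(), k = C.nrow();
  std::vector<double> d2(n);
  int first = (int)(unif_rand() * n);
  if (first >= n) first = n - 1;
  for (int j = 0; j < d; ++j) C(0, j) = X(first, j);
  for (int i = 0; i < n; ++i) d2[i] = row_center_d2(X, i, C, 0);
  for (int c = 1; c < k; ++c) {
    double total = 0.0;
    for (int i = 0; i < n; ++i) total += d2[i];
    int pick;
    if (total <= 0.0) {
      pick = (int)(unif_rand() * n);
      if (pick >= n) pick = n - 1;
    } else {
      const double u = unif_rand() * total;
      double cum = 0.0;
      pick = n - 1;
      for (int i = 0; i < n; ++i) {
        cum += d2[i];
        if (u <= cum) { pick = i; break; }
      }
    }
    for (int j = 0; j < d; ++j) C(c, j) = X(pick, j);
    for (int i = 0; i < n; ++i) {
      const double dd = row_center_d2(X, i, C, c);
      if (dd < d2[i]) d2[i] = dd;
    }
  }
}

// [[Rcpp::export(name = ".kmeans_pp_lloyd")]]
List kmeans_pp_lloyd(NumericMatrix X, int k, int restarts, int max_iter,
                     double tol) {
  const int n = X.nrow(), d = X.ncol();
  if (k < 1 || k > n) stop("k must be between 1 and nrow(X)");
  if (restarts < 1) stop("restarts must be >= 1");

  double best_sse = R_PosInf;
  IntegerVector best_labels(n);
  NumericMatrix best_centers(k, d);
  std::vector<double> best_trace;

  for (int r = 0; r < restarts; ++r) {
    NumericMatrix C(k, d);
    IntegerVector labels(n, -1);
    std::vector<double> trace;
    kmeanspp_init(X, C);
    const double sse = lloyd_run(X, C, labels, max_iter, tol, &trace);
    if (sse < best_sse) {
      best_sse = sse;
      best_labels = clone(labels);
      best_centers = clone(C);
      best_trace = trace;
    }
  }

  for (int i = 0; i < n; ++i) best_labels[i] += 1;  // 1-based labels
  return List::create(_["labels"] = best_labels,
                      _["centers"] = best_centers,
                      _["sse"] = best_sse,
                      _["sse_trace"] = NumericVector(best_trace.begin(),
                                                     best_trace.end()));
}
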