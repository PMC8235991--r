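#include <Rcpp.h>
using namespace Rcpp;

// Dual C-SVC solver: SMO with a cached decision-value vector and Platt's
// max-|Ei-Ej| second-choice heuristic (deterministic; falls back to a full
// scan when the heuristic pair makes no progress). Adequate for the small
// feature tables this package trains on (n of order a few hundred).

static inline double clip(double a, double lo, double hi) {
  return a < lo ? lo : (a > hi ? hi : a);
}

// [[Rcpp::export]]
List cpp_svm_smo(NumericMatrix K, NumericVector y, double C, double tol,
                 int max_passes, int seed) {
  const int n = K.nrow();
  NumericVector alpha(n);
  std::vector<double> f(n, 0.0);  // f[t] = sum_s alpha_s y_s K(s,t), no bias
  double b = 0.0;
  (void)seed;                      // solver is deterministic
  int passes = 0, sweeps = 0;
  const int max_sweeps = 1000;

  // attempt a joint update of (i, j); returns true on progress
  auto try_pair = [&](int i, int j) -> bool {
    if (i == j) return false;
    double Ei = f[i] + b - y[i];
    double Ej = f[j] + b - y[j];
    double ai_old = alpha[i], aj_old = alpha[j];
    double L, H;
    if (y[i] != y[j]) {
      L = std::max(0.0, aj_old - ai_old);
      H = std::min(C, C + aj_old - ai_old);
    } else {
      L = std::max(0.0, ai_old + aj_old - C);
      H = std::min(C, ai_old + aj_old);
    }
    if (L >= H) return false;
    double eta = 2.0 * K(i, j) - K(i, i) - K(j, j);
    if (eta >= 0) return false;
    double aj = clip(aj_old - y[j] * (Ei - Ej) / eta, L, H);
    if (std::fabs(aj - aj_old) < 1e-12) return false;
    double ai = ai_old + y[i] * y[j] * (aj_old - aj);
    alpha[i] = ai;
    alpha[j] = aj;
    double di = (ai - ai_old) * y[i], dj = (aj - aj_old) * y[j];
    for (int t = 0; t < n; ++t) f[t] += di * K(i, t) + dj * K(j, t);
    double b1 = b - Ei - di * K(i, i) - dj * K(i, j);
    double b2 = b - Ej - di * K(i, j) - dj * K(j, j);
    if (ai > 0 && ai < C)
      b = b1;
    else if (aj > 0 && aj < C)
      b = b2;
    else
      b = 0.5 * (b1 + b2);
    return true;
  };

  while (passes < max_passes && sweeps < max_sweeps) {
    ++sweeps;
    int num_changed = 0;
    for (int i = 0; i < n; ++i) {
      double Ei = f[i] + b - y[i];
      if (!((y[i] * Ei < -tol && alpha[i] < C) ||
            (y[i] * Ei > tol && alpha[i] > 0)))
        continue;
      // heuristic second index: maximize |Ei - Ej|
      int jbest = -1;
      double gap = -1.0;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double g = std::fabs(Ei - (f[j] + b - y[j]));
        if (g > gap) {
          gap = g;
          jbest = j;
        }
      }
      bool ok = jbest >= 0 && try_pair(i, jbest);
      if (!ok)
        for (int j = 0; j < n && !ok; ++j)
          if (j != jbest) ok = try_pair(i, j);
      if (ok) ++num_changed;
    }
    if (num_changed == 0)
      ++passes;
    else
      passes = 0;
  }
  return List::create(_["alpha"] = alpha, _["b"] = b, _["sweeps"] = sweeps);
}
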