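#include <Rcpp.h>
using namespace Rcpp;

// Euler–Maruyama first-passage simulation of a symmetric two-boundary
// Wiener process, one row per trial. Evidence starts at a/2 between
// boundaries 0 (error) and a (correct); drift v points to the correct
// boundary. Within each step a Brownian-bridge crossing check removes the
// boundary-overshoot bias of plain Euler (crossing probability
// exp(-2*d0*d1/(s^2*dt)) for distances d0, d1 to the boundary at the step's
// ends). Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
DataFrame ddm_fpt_cpp(NumericVector v, NumericVector a, NumericVector ter,
                      double s, double dt, double tmax) {
  int n = v.size();
  if (a.size() != n || ter.size() != n)
    stop("v, a, ter must have equal length");
  IntegerVector correct(n);
  NumericVector rt(n);
  double sdt = s * std::sqrt(dt);
  for (int i = 0; i < n; ++i) {
    double ai = a[i];
    if (ai <= 0) stop("non-positive boundary separation");
    double x = ai / 2.0, t = 0.0, mu = v[i] * dt;
    int out = NA_INTEGER;
    while (t < tmax) {
      double x1 = x + mu + sdt * norm_rand();
      t += dt;
      if (x1 >= ai) { out = 1; break; }
      if (x1 <= 0.0) { out = 0; break; }
      // bridge crossing probabilities for each boundary within the step
      double pu = std::exp(-2.0 * (ai - x) * (ai - x1) / (s * s * dt));
      if (unif_rand() < pu) { out = 1; break; }
      double pl = std::exp(-2.0 * x * x1 / (s * s * dt));
      if (unif_rand() < pl) { out = 0; break; }
      x = x1;
    }
    if (out == NA_INTEGER) { // censored at tmax: call by current position
      out = x >= ai / 2.0 ? 1 : 0;
      t = tmax;
    }
    correct[i] = out;
    rt[i] = t + ter[i];
  }
  return DataFrame::create(_["correct"] = correct, _["rt"] = rt);
}
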