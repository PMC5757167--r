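#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for
//   min_a ||y - A a||_2^2 + sum_j 2 * thr_j * |a_j|
// parameterized by the Gram matrix G = A'A and g0 = A'y (covariance
// updates), so each coordinate update is O(n) regardless of the atom
// dimension. thr_j = mu * w_j / 2 is the soft threshold of coordinate j;
// thr_j = 0 leaves that coordinate unregularized. Deterministic: starts at
// zero, visits coordinates in order.
// [[Rcpp::export]]
List cd_weighted_l1(const NumericMatrix& G, const NumericVector& g0,
                    const NumericVector& thr, double tol, int max_iter) {
  const int n = G.ncol();
  NumericVector a(n);
  NumericVector g = clone(g0);   // g = A'(y - A a)
  bool converged = false;
  int iter = 0;
  while (iter < max_iter) {
    ++iter;
    double delta_max = 0.0;
    for (int j = 0; j < n; ++j) {
      const double dj = G(j, j);
      if (dj == 0.0) continue;
      const double z = g[j] + dj * a[j];
      double a_new = 0.0;
      const double az = std::fabs(z) - thr[j];
      if (az > 0.0) a_new = (z > 0 ? az : -az) / dj;
      if (a_new != a[j]) {
        const double diff = a_new - a[j];
        const double* Gj = &G(0, j);
        for (int i = 0; i < n; ++i) g[i] -= Gj[i] * diff;
        const double ad = std::fabs(diff);
        if (ad > delta_max) delta_max = ad;
        a[j] = a_new;
      }
    }
    if (delta_max < tol) { converged = true; break; }
  }
  return List::create(_["a"] = a, _["iterations"] = iter,
                      _["converged"] = converged);
}
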