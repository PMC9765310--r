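// Fused Adam update: single pass over the parameter block instead of a
// chain of R-level vectorized temporaries.  Returns fresh arrays (the
// caller replaces its copies), bias correction applied at step t.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List adam_fused(NumericVector w, NumericVector g, NumericVector m,
                NumericVector v, double lr, double beta1, double beta2,
                double eps, int t) {
  const R_xlen_t n = w.size();
  NumericVector w2(n), m2(n), v2(n);
  const double bc1 = 1.0 - std::pow(beta1, t);
  const double bc2 = 1.0 - std::pow(beta2, t);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double mi = beta1 * m[i] + (1.0 - beta1) * g[i];
    const double vi = beta2 * v[i] + (1.0 - beta2) * g[i] * g[i];
    m2[i] = mi;
    v2[i] = vi;
    w2[i] = w[i] - lr * (mi / bc1) / (std::sqrt(vi / bc2) + eps);
  }
  w2.attr("dim") = w.attr("dim");
  return List::create(Named("w") = w2, Named("m") = m2, Named("v") = v2);
}
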