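#include <Rcpp.h>
using namespace Rcpp;

// In-place Adam update for one parameter block. W, m and v are modified in
// place (the caller owns deep copies), which avoids allocating ~10
// temporaries per step on the large input-side weight matrices.
// [[Rcpp::export(name = ".adamStep")]]
void adamStep(NumericVector W, NumericVector m, NumericVector v,
              NumericVector g, double lr, double beta1, double beta2,
              double eps, double corr1, double corr2) {
  const R_xlen_t n = W.size();
  const double ib1 = 1.0 - beta1, ib2 = 1.0 - beta2;
  const double isc2 = 1.0 / std::sqrt(corr2);
  const double step = lr / corr1;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = g[i];
    const double mi = beta1 * m[i] + ib1 * gi;
    const double vi = beta2 * v[i] + ib2 * gi * gi;
    m[i] = mi;
    v[i] = vi;
    W[i] -= step * mi / (std::sqrt(vi) * isc2 + eps);
  }
}
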