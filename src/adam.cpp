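#include <Rcpp.h>
using namespace Rcpp;

// Fused in-place Adam update: one pass over the parameter block, no
// temporaries. The caller owns the buffers and guarantees they are not
// aliased elsewhere (the target network is deep-copied on sync).
// [[Rcpp::export(name = ".adam_step")]]
void adam_step(NumericVector W, NumericVector m, NumericVector v,
               NumericVector g, double lr, double b1, double b2,
               double eps, double c1, double c2) {
  const R_xlen_t n = W.size();
  double *w = W.begin(), *mm = m.begin(), *vv = v.begin(), *gg = g.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = gg[i];
    mm[i] = b1 * mm[i] + (1.0 - b1) * gi;
    vv[i] = b2 * vv[i] + (1.0 - b2) * gi * gi;
    w[i] -= lr * (mm[i] / c1) / (std::sqrt(vv[i] / c2) + eps);
  }
}
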