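// Fused deep-Q update: forward passes (online + target), double-Q target,
// Huber loss on the taken actions, backprop through the ReLU stack, and an
// in-place Adam step — one call per minibatch, no R-level temporaries.
// Weight matrices are modified in place; the caller guarantees the online
// and target parameter buffers are never aliased.

#include <RcppArmadillo.h>
#include <xmmintrin.h>
#include <pmmintrin.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Adam's exponentially decaying moments reach denormal magnitude for inputs
// with (near-)zero gradients after a few thousand updates, and denormal
// arithmetic runs via microcode assists — the update slows down several-fold
// as training progresses. Flush-to-zero / denormals-are-zero mode inside the
// kernel removes the stall; the caller's FP environment is restored on exit.
struct FlushDenormals {
  unsigned int csr;
  FlushDenormals() : csr(_mm_getcsr()) {
    _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
    _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
  }
  ~FlushDenormals() { _mm_setcsr(csr); }
};

static arma::mat view(SEXP m) {
  NumericMatrix nm(m);
  return arma::mat(nm.begin(), nm.nrow(), nm.ncol(), false, true);
}
static arma::vec viewv(SEXP v) {
  NumericVector nv(v);
  return arma::vec(nv.begin(), nv.size(), false, true);
}

// forward through ReLU hidden layers; optionally keep pre-activations
static arma::mat forward(List W, List b, const arma::mat& X,
                         std::vector<arma::mat>* Zs,
                         std::vector<arma::mat>* As) {
  const int L = W.size();
  arma::mat A = X;
  for (int l = 0; l < L; ++l) {
    arma::mat Wl = view(W[l]);
    arma::vec bl = viewv(b[l]);
    if (As) As->push_back(A);
    arma::mat Z = Wl * A;
    Z.each_col() += bl;
    if (l < L - 1) {
      if (Zs) Zs->push_back(Z);
      A = arma::clamp(Z, 0.0, arma::datum::inf);
    } else {
      A = Z;
    }
  }
  return A;
}

// single fused pass; the rsqrt form avoids one division per parameter
static void adam(arma::mat& P, arma::mat& m, arma::mat& v, const arma::mat& g,
                 double lr, double b1, double b2, double eps,
                 double c1, double c2) {
  const arma::uword n = P.n_elem;
  double *p = P.memptr(), *mm = m.memptr(), *vv = v.memptr();
  const double *gg = g.memptr();
  for (arma::uword i = 0; i < n; ++i) {
    const double gi = gg[i];
    const double mi = b1 * mm[i] + (1.0 - b1) * gi;
    const double vi = b2 * vv[i] + (1.0 - b2) * gi * gi;
    mm[i] = mi; vv[i] = vi;
    p[i] -= lr * (mi / c1) / (std::sqrt(vi / c2) + eps);
  }
}

// [[Rcpp::export(name = ".qnet_update_cpp")]]
double qnet_update_cpp(List W, List b, List mW, List vW, List mb, List vb,
                       List Wt, List bt,
                       const arma::mat& X, const arma::mat& Xn,
                       const arma::ivec& actions, const arma::vec& rewards,
                       const arma::vec& disc, const arma::vec& done,
                       double lr, double huber, int t,
                       double beta1, double beta2, double eps) {
  FlushDenormals ftz;
  const int L = W.size();
  const arma::uword B = X.n_cols;

  std::vector<arma::mat> Zs, As;
  Zs.reserve(L); As.reserve(L);
  arma::mat Q = forward(W, b, X, &Zs, &As);
  arma::mat Qn_online = forward(W, b, Xn, nullptr, nullptr);
  arma::mat Qn_target = forward(Wt, bt, Xn, nullptr, nullptr);

  // double-Q target: online argmax, target value
  arma::vec tgt(B), err(B);
  double loss = 0.0;
  arma::mat dZ(Q.n_rows, B, arma::fill::zeros);
  for (arma::uword j = 0; j < B; ++j) {
    arma::uword amax;
    Qn_online.col(j).max(amax);
    tgt(j) = rewards(j) + disc(j) * Qn_target(amax, j) * (1.0 - done(j));
    const int a = actions(j) - 1;
    const double e = Q(a, j) - tgt(j);
    const double ae = std::fabs(e);
    loss += (ae <= huber) ? 0.5 * e * e : huber * (ae - 0.5 * huber);
    dZ(a, j) = std::max(-huber, std::min(huber, e)) / double(B);
  }
  loss /= double(B);

  const double c1 = 1.0 - std::pow(beta1, t);
  const double c2 = 1.0 - std::pow(beta2, t);
  for (int l = L - 1; l >= 0; --l) {
    arma::mat dW = dZ * As[l].t();
    arma::vec db = arma::sum(dZ, 1);
    if (l > 0) {
      arma::mat Wl = view(W[l]);
      arma::mat dA = Wl.t() * dZ;
      dZ = dA % arma::conv_to<arma::mat>::from(Zs[l - 1] > 0);
    }
    arma::mat Wl = view(W[l]), mWl = view(mW[l]), vWl = view(vW[l]);
    adam(Wl, mWl, vWl, dW, lr, beta1, beta2, eps, c1, c2);
    arma::vec bl = viewv(b[l]), mbl = viewv(mb[l]), vbl = viewv(vb[l]);
    arma::mat bm(bl.memptr(), bl.n_elem, 1, false, true);
    arma::mat mbm(mbl.memptr(), mbl.n_elem, 1, false, true);
    arma::mat vbm(vbl.memptr(), vbl.n_elem, 1, false, true);
    adam(bm, mbm, vbm, arma::mat(db.memptr(), db.n_elem, 1, false, true),
         lr, beta1, beta2, eps, c1, c2);
  }
  return loss;
}
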