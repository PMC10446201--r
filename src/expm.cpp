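// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// Dense matrix exponential (scaling-and-squaring Pade), used for the
// consensus/advection kernels exp(-t * L). Kept in C++ because the kernel
// is recomputed at every functional rewiring step.
// [[Rcpp::export]]
arma::mat expm_dense(const arma::mat& M) {
  return arma::expmat(M);
}
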