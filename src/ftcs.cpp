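#include <Rcpp.h>
using namespace Rcpp;

// Conservative FTCS diffusion on the 4-neighbor stencil with
// precomputed interface coefficients (already scaled by dt_sub / h^2).
// Dv: (nr-1) x nc vertical-edge coefficients, Dh: nr x (nc-1)
// horizontal-edge coefficients; both are 0 across impermeable
// boundaries, which gives zero-flux sector borders for free.
// [[Rcpp::export(name = ".ftcs_diffuse_cpp")]]
NumericMatrix ftcs_diffuse_cpp(NumericMatrix A_in, NumericMatrix Dv,
                               NumericMatrix Dh, int n_sub) {
  NumericMatrix A = clone(A_in);
  const int nr = A.nrow(), nc = A.ncol();
  NumericMatrix delta(nr, nc);
  for (int s = 0; s < n_sub; ++s) {
    std::fill(delta.begin(), delta.end(), 0.0);
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i + 1 < nr; ++i) {
        const double f = Dv(i, j) * (A(i + 1, j) - A(i, j));
        delta(i, j) += f;
        delta(i + 1, j) -= f;
      }
    }
    for (int j = 0; j + 1 < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        const double f = Dh(i, j) * (A(i, j + 1) - A(i, j));
        delta(i, j) += f;
        delta(i, j + 1) -= f;
      }
    }
    for (int k = 0; k < nr * nc; ++k) A[k] += delta[k];
  }
  return A;
}
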