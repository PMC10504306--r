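// Per-voxel symmetric 3x3 eigendecomposition for tensor volumes.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// tensors: n x 6 matrix, component order (xx, yy, zz, xy, xz, yz).
// Returns values (n x 3, descending) and vectors (n x 9, columns
// e1x, e1y, e1z, e2x, ..., e3z), eigenvectors unit-norm and orthogonal.
// [[Rcpp::export]]
List eig_sym_vol(const NumericMatrix &tensors) {
  const int n = tensors.nrow();
  NumericMatrix values(n, 3);
  NumericMatrix vectors(n, 9);
  arma::mat33 D;
  arma::vec3 ev;
  arma::mat33 evec;
  for (int i = 0; i < n; ++i) {
    const double xx = tensors(i, 0), yy = tensors(i, 1), zz = tensors(i, 2);
    const double xy = tensors(i, 3), xz = tensors(i, 4), yz = tensors(i, 5);
    D(0, 0) = xx; D(1, 1) = yy; D(2, 2) = zz;
    D(0, 1) = D(1, 0) = xy;
    D(0, 2) = D(2, 0) = xz;
    D(1, 2) = D(2, 1) = yz;
    arma::eig_sym(ev, evec, D);  // ascending
    for (int e = 0; e < 3; ++e) {
      const int src = 2 - e;     // descending
      values(i, e) = ev(src);
      for (int c = 0; c < 3; ++c) vectors(i, 3 * e + c) = evec(c, src);
    }
  }
  return List::create(_["values"] = values, _["vectors"] = vectors);
}
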