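// Compiled kernels for the 1-D convolution layer (im2col gather + GEMM and
// the matching backward scatter). Only the convolution is compiled: it
// dominates the training cost; everything else stays in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// x: (C, L, B) array; W: (C_out, C*k); returns y (C_out, L, B) and the
// im2col matrix A (C*k, L*B) for reuse in the backward pass.
// [[Rcpp::export(name = ".cpp_conv1d_fwd")]]
List cpp_conv1d_fwd(NumericVector x, NumericMatrix W, NumericVector b,
                    int k, int dilation, int pad_left) {
  IntegerVector dims = x.attr("dim");
  const int C = dims[0], L = dims[1], B = dims[2];
  const int Cout = W.nrow();
  arma::cube xc(x.begin(), C, L, B, false, true);
  arma::mat Wm(W.begin(), Cout, W.ncol(), false, true);
  arma::vec bv(b.begin(), b.size(), false, true);

  arma::mat A(C * k, (size_t)L * B, arma::fill::zeros);
  for (int bi = 0; bi < B; ++bi) {
    const arma::mat& slab = xc.slice(bi);
    for (int t = 0; t < L; ++t) {
      double* col = A.colptr((size_t)bi * L + t);
      for (int j = 0; j < k; ++j) {
        int src = t + j * dilation - pad_left;   // position in unpadded input
        if (src >= 0 && src < L) {
          const double* s = slab.colptr(src);
          std::copy(s, s + C, col + (size_t)j * C);
        }
      }
    }
  }
  arma::mat Y = Wm * A;
  Y.each_col() += bv;
  NumericVector yout(Y.begin(), Y.end());
  yout.attr("dim") = IntegerVector::create(Cout, L, B);
  return List::create(_["y"] = yout, _["A"] = wrap(A));
}

// dy: (C_out, L, B); A: cached im2col matrix; returns dW, db, dx.
// [[Rcpp::export(name = ".cpp_conv1d_bwd")]]
List cpp_conv1d_bwd(NumericVector dy, NumericMatrix W, NumericMatrix A,
                    int C, int k, int dilation, int pad_left) {
  IntegerVector dims = dy.attr("dim");
  const int Cout = dims[0], L = dims[1], B = dims[2];
  arma::mat dY(dy.begin(), Cout, (size_t)L * B, false, true);
  arma::mat Wm(W.begin(), Cout, W.ncol(), false, true);
  arma::mat Am(A.begin(), A.nrow(), A.ncol(), false, true);

  arma::mat dW = dY * Am.t();
  arma::vec db = arma::sum(dY, 1);
  arma::mat dA = Wm.t() * dY;                    // (C*k, L*B)

  NumericVector dx(C * (size_t)L * B);
  arma::cube dxc(dx.begin(), C, L, B, false, true);
  for (int bi = 0; bi < B; ++bi) {
    arma::mat& slab = dxc.slice(bi);
    for (int t = 0; t < L; ++t) {
      const double* col = dA.colptr((size_t)bi * L + t);
      for (int j = 0; j < k; ++j) {
        int src = t + j * dilation - pad_left;
        if (src >= 0 && src < L) {
          double* s = slab.colptr(src);
          const double* c0 = col + (size_t)j * C;
          for (int c = 0; c < C; ++c) s[c] += c0[c];
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(C, L, B);
  return List::create(_["dW"] = wrap(dW), _["db"] = wrap(db),
                      _["dx"] = dx);
}
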