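// 3x3 convolution forward/backward via im2col + GEMM (Armadillo/BLAS).
// Feature maps are (channels) x (h*w*n) matrices, positions flattened
// row-fastest (j = r + c*h), samples in contiguous column blocks.
// 'Same' zero padding: taps whose source falls outside the frame
// contribute zero. Tap order (outer v = column offset, inner u = row
// offset) must match the R-side kernel packing in conv_pack_weights().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void im2col3(const arma::mat& X, int h, int w,
                    int stride, int dil, arma::mat& cols) {
  const int cin = X.n_rows;
  const int ho = h / stride, wo = w / stride;
  cols.zeros();
  int t = 0;
  for (int v = -1; v <= 1; ++v) {
    for (int u = -1; u <= 1; ++u, ++t) {
      // valid output rows/cols: 0 <= r_out*stride + u*dil <= h-1
      int r0 = 0, r1 = ho - 1, c0 = 0, c1 = wo - 1;
      while (r0 <= r1 && r0 * stride + u * dil < 0) ++r0;
      while (r1 >= r0 && r1 * stride + u * dil > h - 1) --r1;
      while (c0 <= c1 && c0 * stride + v * dil < 0) ++c0;
      while (c1 >= c0 && c1 * stride + v * dil > w - 1) --c1;
      if (r0 > r1 || c0 > c1) continue;
      for (int c = c0; c <= c1; ++c) {
        const int ci = c * stride + v * dil;
        if (stride == 1) {
          cols.submat(t * cin, r0 + c * ho, t * cin + cin - 1, r1 + c * ho) =
            X.cols(ci * h + r0 + u * dil, ci * h + r1 + u * dil);
        } else {
          for (int r = r0; r <= r1; ++r)
            cols.col(r + c * ho).subvec(t * cin, t * cin + cin - 1) =
              X.col(ci * h + r * stride + u * dil);
        }
      }
    }
  }
}

static void col2im3(const arma::mat& dcols, int h, int w,
                    int stride, int dil, arma::mat& dX) {
  const int cin = dX.n_rows;
  const int ho = h / stride, wo = w / stride;
  int t = 0;
  for (int v = -1; v <= 1; ++v) {
    for (int u = -1; u <= 1; ++u, ++t) {
      int r0 = 0, r1 = ho - 1, c0 = 0, c1 = wo - 1;
      while (r0 <= r1 && r0 * stride + u * dil < 0) ++r0;
      while (r1 >= r0 && r1 * stride + u * dil > h - 1) --r1;
      while (c0 <= c1 && c0 * stride + v * dil < 0) ++c0;
      while (c1 >= c0 && c1 * stride + v * dil > w - 1) --c1;
      if (r0 > r1 || c0 > c1) continue;
      for (int c = c0; c <= c1; ++c) {
        const int ci = c * stride + v * dil;
        if (stride == 1) {
          dX.cols(ci * h + r0 + u * dil, ci * h + r1 + u * dil) +=
            dcols.submat(t * cin, r0 + c * ho, t * cin + cin - 1, r1 + c * ho);
        } else {
          for (int r = r0; r <= r1; ++r)
            dX.col(ci * h + r * stride + u * dil) +=
              dcols.col(r + c * ho).subvec(t * cin, t * cin + cin - 1);
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat conv3_fwd_cpp(const arma::mat& W2, const arma::vec& b,
                        const arma::mat& x, int h, int w, int n,
                        int stride, int dil) {
  const int cin = x.n_rows;
  const int cout = W2.n_rows;
  const int ho = h / stride, wo = w / stride;
  arma::mat y(cout, ho * wo * n);
  arma::mat cols(9 * cin, ho * wo);
  for (int s = 0; s < n; ++s) {
    arma::mat X = x.cols(s * h * w, (s + 1) * h * w - 1);
    im2col3(X, h, w, stride, dil, cols);
    y.cols(s * ho * wo, (s + 1) * ho * wo - 1) = W2 * cols;
  }
  y.each_col() += b;
  return y;
}

// [[Rcpp::export]]
List conv3_bwd_cpp(const arma::mat& W2, const arma::mat& x,
                   const arma::mat& dy, int h, int w, int n,
                   int stride, int dil) {
  const int cin = x.n_rows;
  const int ho = h / stride, wo = w / stride;
  arma::mat dW2(W2.n_rows, W2.n_cols, arma::fill::zeros);
  arma::mat dx(cin, h * w * n, arma::fill::zeros);
  arma::mat cols(9 * cin, ho * wo);
  for (int s = 0; s < n; ++s) {
    arma::mat X = x.cols(s * h * w, (s + 1) * h * w - 1);
    arma::mat dys = dy.cols(s * ho * wo, (s + 1) * ho * wo - 1);
    im2col3(X, h, w, stride, dil, cols);
    dW2 += dys * cols.t();
    arma::mat dcols = W2.t() * dys;
    arma::mat dXs(dx.colptr(s * h * w), cin, h * w, false, true);
    col2im3(dcols, h, w, stride, dil, dXs);
  }
  arma::vec db = arma::sum(dy, 1);
  return List::create(Named("dW2") = dW2, Named("db") = db,
                      Named("dx") = dx);
}
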