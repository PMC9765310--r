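// Low-level im2col / col2im primitives behind every convolution in the
// package.  Layout conventions (fixed, relied on by R/nn-layers.R):
//   * feature maps are H x W x C cubes (column-major, matching R arrays);
//   * im2col rows are indexed ki + kj*k + c*k*k, i.e. the column-major
//     flattening of a (k, k, C) window, so a weight array of dim
//     (k, k, C_in, C_out) flattens to a conformable (k*k*C_in, C_out) matrix;
//   * im2col columns are indexed i + j*Ho, the column-major flattening of
//     the output grid, so a (Ho*Wo, C_out) product reshapes directly into an
//     (Ho, Wo, C_out) array.
// col2im is the exact adjoint of im2col (scatter-add), which is what makes
// it serve both as the conv input-gradient and the transposed-conv forward.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static inline int out_extent(int n, int k, int stride, int pad, int dilation) {
  int keff = (k - 1) * dilation + 1;
  return (n + 2 * pad - keff) / stride + 1;
}

// [[Rcpp::export]]
arma::mat nn_im2col(const arma::cube& x, int k, int stride, int pad,
                    int dilation) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = out_extent(H, k, stride, pad, dilation);
  const int Wo = out_extent(W, k, stride, pad, dilation);
  arma::mat cols(k * k * C, Ho * Wo, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + kj * k + c * k * k;
        for (int j = 0; j < Wo; ++j) {
          const int wj = j * stride - pad + kj * dilation;
          if (wj < 0 || wj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int wi = i * stride - pad + ki * dilation;
            if (wi < 0 || wi >= H) continue;
            cols(r, i + j * Ho) = x(wi, wj, c);
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
arma::cube nn_col2im(const arma::mat& cols, int H, int W, int C, int k,
                     int stride, int pad, int dilation) {
  const int Ho = out_extent(H, k, stride, pad, dilation);
  const int Wo = out_extent(W, k, stride, pad, dilation);
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + kj * k + c * k * k;
        for (int j = 0; j < Wo; ++j) {
          const int wj = j * stride - pad + kj * dilation;
          if (wj < 0 || wj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int wi = i * stride - pad + ki * dilation;
            if (wi < 0 || wi >= H) continue;
            x(wi, wj, c) += cols(r, i + j * Ho);
          }
        }
      }
    }
  }
  return x;
}
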