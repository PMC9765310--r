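// Fused convolution / transposed-convolution layers: one C++ call per
// forward or backward pass (im2col + GEMM + bias + activation), avoiding
// intermediate copies across the R boundary.  The backward pass needs only
// the layer input and output: for every activation used here the derivative
// is recoverable from the output (relu/lrelu: sign; sigmoid: a(1-a)).
// Activation codes: 0 linear, 1 relu, 2 lrelu, 3 sigmoid.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_extent_f(int n, int k, int stride, int pad,
                               int dilation) {
  int keff = (k - 1) * dilation + 1;
  return (n + 2 * pad - keff) / stride + 1;
}

// Loop order: output pixel outer, patch-row inner, so writes run
// contiguously down each column of `cols`.
static arma::mat im2col_(const arma::cube& x, int k, int stride, int pad,
                         int dilation) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = out_extent_f(H, k, stride, pad, dilation);
  const int Wo = out_extent_f(W, k, stride, pad, dilation);
  const int HW = H * W;
  arma::mat cols(k * k * C, Ho * Wo, arma::fill::zeros);
  const double* xp = x.memptr();
  for (int j = 0; j < Wo; ++j) {
    for (int i = 0; i < Ho; ++i) {
      double* col = cols.colptr(i + j * Ho);
      const int i0 = i * stride - pad, j0 = j * stride - pad;
      for (int c = 0; c < C; ++c) {
        const double* xc = xp + c * HW;
        for (int kj = 0; kj < k; ++kj) {
          const int wj = j0 + kj * dilation;
          if (wj < 0 || wj >= W) continue;
          const double* xcol = xc + wj * H;
          double* dst = col + c * k * k + kj * k;
          for (int ki = 0; ki < k; ++ki) {
            const int wi = i0 + ki * dilation;
            if (wi >= 0 && wi < H) dst[ki] = xcol[wi];
          }
        }
      }
    }
  }
  return cols;
}

static arma::cube col2im_(const arma::mat& cols, int H, int W, int C, int k,
                          int stride, int pad, int dilation) {
  const int Ho = out_extent_f(H, k, stride, pad, dilation);
  const int Wo = out_extent_f(W, k, stride, pad, dilation);
  const int HW = H * W;
  arma::cube x(H, W, C, arma::fill::zeros);
  double* xp = x.memptr();
  for (int j = 0; j < Wo; ++j) {
    for (int i = 0; i < Ho; ++i) {
      const double* col = cols.colptr(i + j * Ho);
      const int i0 = i * stride - pad, j0 = j * stride - pad;
      for (int c = 0; c < C; ++c) {
        double* xc = xp + c * HW;
        for (int kj = 0; kj < k; ++kj) {
          const int wj = j0 + kj * dilation;
          if (wj < 0 || wj >= W) continue;
          double* xcol = xc + wj * H;
          const double* src = col + c * k * k + kj * k;
          for (int ki = 0; ki < k; ++ki) {
            const int wi = i0 + ki * dilation;
            if (wi >= 0 && wi < H) xcol[wi] += src[ki];
          }
        }
      }
    }
  }
  return x;
}

static void act_inplace(arma::mat& z, int act, double slope) {
  switch (act) {
  case 0: break;
  case 1: z.transform([](double v) { return v > 0 ? v : 0.0; }); break;
  case 2: z.transform([slope](double v) { return v > 0 ? v : slope * v; });
    break;
  case 3: z.transform([](double v) { return 1.0 / (1.0 + std::exp(-v)); });
    break;
  }
}

// multiply grad by activation derivative recovered from the output a
static void act_grad_inplace(arma::mat& g, const arma::mat& a, int act,
                             double slope) {
  switch (act) {
  case 0: break;
  case 1: g %= arma::conv_to<arma::mat>::from(a > 0); break;
  case 2: {
    arma::mat m = arma::conv_to<arma::mat>::from(a > 0);
    g %= m + slope * (1.0 - m);
    break;
  }
  case 3: g %= a % (1.0 - a); break;
  }
}

// [[Rcpp::export]]
arma::cube conv_fwd(const arma::cube& x, const arma::mat& W,
                    const arma::vec& b, int k, int stride, int pad,
                    int dilation, int act, double slope) {
  const int Ho = out_extent_f(x.n_rows, k, stride, pad, dilation);
  const int Wo = out_extent_f(x.n_cols, k, stride, pad, dilation);
  arma::mat cols = im2col_(x, k, stride, pad, dilation);
  arma::mat z = cols.t() * W;           // (Ho*Wo) x Cout
  z.each_row() += b.t();
  act_inplace(z, act, slope);
  return arma::cube(z.memptr(), Ho, Wo, W.n_cols);
}

// [[Rcpp::export]]
List conv_bwd(const arma::cube& x, const arma::cube& a, const arma::mat& W,
              const arma::cube& grad_out, int k, int stride, int pad,
              int dilation, int act, double slope, bool need_gx = true) {
  const int cout = W.n_cols;
  const int P = grad_out.n_rows * grad_out.n_cols;
  arma::mat G(const_cast<double*>(grad_out.memptr()), P, cout, true);
  arma::mat A(const_cast<double*>(a.memptr()), P, cout, false);
  act_grad_inplace(G, A, act, slope);
  arma::mat cols = im2col_(x, k, stride, pad, dilation);
  arma::mat gW = cols * G;
  arma::vec gb = arma::sum(G, 0).t();
  if (!need_gx) {
    return List::create(Named("gx") = R_NilValue, Named("gW") = gW,
                        Named("gb") = gb);
  }
  arma::mat gcols = W * G.t();
  arma::cube gx = col2im_(gcols, x.n_rows, x.n_cols, x.n_slices, k, stride,
                          pad, dilation);
  return List::create(Named("gx") = gx, Named("gW") = gW, Named("gb") = gb);
}

// [[Rcpp::export]]
arma::cube tconv_fwd(const arma::cube& x, const arma::mat& W,
                     const arma::vec& b, int k, int stride, int pad, int act,
                     double slope) {
  const int cin = x.n_slices;
  const int Ho = (x.n_rows - 1) * stride - 2 * pad + k;
  const int Wo = (x.n_cols - 1) * stride - 2 * pad + k;
  const int cout = W.n_rows / (k * k);
  arma::mat Xm(const_cast<double*>(x.memptr()), x.n_rows * x.n_cols, cin,
               false);
  arma::mat cols = W * Xm.t();
  arma::cube z = col2im_(cols, Ho, Wo, cout, k, stride, pad, 1);
  for (int c = 0; c < cout; ++c) z.slice(c) += b(c);
  arma::mat zm(z.memptr(), Ho * Wo, cout, false);
  act_inplace(zm, act, slope);
  return z;
}

// [[Rcpp::export]]
List tconv_bwd(const arma::cube& x, const arma::cube& a, const arma::mat& W,
               const arma::cube& grad_out, int k, int stride, int pad,
               int act, double slope, bool need_gx = true) {
  const int cin = x.n_slices;
  const int cout = grad_out.n_slices;
  const int P = grad_out.n_rows * grad_out.n_cols;
  arma::cube g = grad_out;  // copy; modified in place
  arma::mat gm(g.memptr(), P, cout, false);
  arma::mat A(const_cast<double*>(a.memptr()), P, cout, false);
  act_grad_inplace(gm, A, act, slope);
  arma::mat gcols = im2col_(g, k, stride, pad, 1);
  arma::mat Xm(const_cast<double*>(x.memptr()), x.n_rows * x.n_cols, cin,
               false);
  arma::mat gW = gcols * Xm;
  arma::vec gb = arma::sum(gm, 0).t();
  if (!need_gx) {
    return List::create(Named("gx") = R_NilValue, Named("gW") = gW,
                        Named("gb") = gb);
  }
  arma::mat gX = (W.t() * gcols).t();
  arma::cube gxc(gX.memptr(), x.n_rows, x.n_cols, cin);
  return List::create(Named("gx") = gxc, Named("gW") = gW, Named("gb") = gb);
}
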