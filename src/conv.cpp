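// 2D convolution primitives (im2col + GEMM) used by the autograd tape.
// Arrays are H x W x C (column-major, matching R). Conv weights are stored
// as (kh*kw*Cin) x Cout matrices whose row index runs over (ky, kx, c) in
// column-major order, i.e. the flattening of an R array dim c(kh, kw, Cin).

#include <RcppArmadillo.h>
using namespace arma;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

static mat im2col(const cube& x, int kh, int kw, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int oh = out_size(H, kh, stride, pad);
  const int ow = out_size(W, kw, stride, pad);
  mat K(kh * kw * C, oh * ow);
  K.zeros();
  for (int ox = 0; ox < ow; ++ox) {
    const int ix0 = ox * stride - pad;
    for (int oy = 0; oy < oh; ++oy) {
      const int iy0 = oy * stride - pad;
      const int j = oy + oh * ox;
      double* col = K.colptr(j);
      for (int c = 0; c < C; ++c) {
        const mat& xc = x.slice(c);
        for (int kx = 0; kx < kw; ++kx) {
          const int ix = ix0 + kx;
          if (ix < 0 || ix >= W) continue;
          for (int ky = 0; ky < kh; ++ky) {
            const int iy = iy0 + ky;
            if (iy < 0 || iy >= H) continue;
            col[ky + kh * (kx + kw * c)] = xc(iy, ix);
          }
        }
      }
    }
  }
  return K;
}

static void col2im(const mat& K, cube& gx, int kh, int kw, int stride, int pad) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  const int oh = out_size(H, kh, stride, pad);
  const int ow = out_size(W, kw, stride, pad);
  for (int ox = 0; ox < ow; ++ox) {
    const int ix0 = ox * stride - pad;
    for (int oy = 0; oy < oh; ++oy) {
      const int iy0 = oy * stride - pad;
      const int j = oy + oh * ox;
      const double* col = K.colptr(j);
      for (int c = 0; c < C; ++c) {
        mat& gc = gx.slice(c);
        for (int kx = 0; kx < kw; ++kx) {
          const int ix = ix0 + kx;
          if (ix < 0 || ix >= W) continue;
          for (int ky = 0; ky < kh; ++ky) {
            const int iy = iy0 + ky;
            if (iy < 0 || iy >= H) continue;
            gc(iy, ix) += col[ky + kh * (kx + kw * c)];
          }
        }
      }
    }
  }
}

// y(oh, ow, Cout) = conv(x, w) + b
// [[Rcpp::export(name = ".cpp_conv2d_fwd")]]
arma::cube cpp_conv2d_fwd(const arma::cube& x, const arma::mat& w,
                          const arma::vec& b, int kh, int kw,
                          int stride, int pad) {
  const int oh = out_size(x.n_rows, kh, stride, pad);
  const int ow = out_size(x.n_cols, kw, stride, pad);
  const int cout = w.n_cols;
  mat K = im2col(x, kh, kw, stride, pad);
  mat o = w.t() * K;           // cout x (oh*ow)
  o.each_col() += b;
  cube y(oh, ow, cout);
  for (int c = 0; c < cout; ++c) {
    y.slice(c) = reshape(o.row(c), oh, ow);
  }
  return y;
}

// gradient w.r.t. the conv input; also the forward pass of the 3x3/stride-2
// transposed convolution (with gy playing the role of the small image)
// [[Rcpp::export(name = ".cpp_conv2d_bwd_input")]]
arma::cube cpp_conv2d_bwd_input(const arma::cube& gy, const arma::mat& w,
                                int kh, int kw, int stride, int pad,
                                int in_h, int in_w) {
  const int oh = gy.n_rows, ow = gy.n_cols, cout = gy.n_slices;
  mat gym(cout, oh * ow);
  for (int c = 0; c < cout; ++c) {
    gym.row(c) = vectorise(gy.slice(c)).t();
  }
  mat cols = w * gym;          // (kh*kw*Cin) x (oh*ow)
  const int cin = w.n_rows / (kh * kw);
  cube gx(in_h, in_w, cin, fill::zeros);
  col2im(cols, gx, kh, kw, stride, pad);
  return gx;
}

// [[Rcpp::export(name = ".cpp_conv2d_bwd_weight")]]
arma::mat cpp_conv2d_bwd_weight(const arma::cube& x, const arma::cube& gy,
                                int kh, int kw, int stride, int pad) {
  const int oh = gy.n_rows, ow = gy.n_cols, cout = gy.n_slices;
  mat gym(cout, oh * ow);
  for (int c = 0; c < cout; ++c) {
    gym.row(c) = vectorise(gy.slice(c)).t();
  }
  mat K = im2col(x, kh, kw, stride, pad);
  return K * gym.t();          // (kh*kw*Cin) x Cout
}
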