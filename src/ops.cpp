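// Low-level numerical kernels: separable Gaussian surround filtering for the
// Retinex enhancer and im2col-based convolution primitives for the
// segmentation network. Tensors are H x W x C arma::cubes (column-major,
// matching R arrays with dim = c(H, W, C)).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// reflect (symmetric, edge included) index into [0, n); folds as often as needed
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// [[Rcpp::export]]
arma::mat cpp_gauss_blur(const arma::mat& x, double sigma) {
  if (sigma <= 0) stop("sigma must be positive");
  const int H = x.n_rows, W = x.n_cols;
  int r = (int)std::ceil(3.0 * sigma);
  if (r < 1) r = 1;
  arma::vec k(2 * r + 1);
  for (int i = -r; i <= r; ++i) k(i + r) = std::exp(-0.5 * (double)i * i / (sigma * sigma));
  k /= arma::accu(k);

  arma::mat tmp(H, W), out(H, W);
  // horizontal pass (along columns index j)
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      double s = 0.0;
      for (int t = -r; t <= r; ++t) s += k(t + r) * x(i, reflect_idx(j + t, W));
      tmp(i, j) = s;
    }
  }
  // vertical pass
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double s = 0.0;
      for (int t = -r; t <= r; ++t) s += k(t + r) * tmp(reflect_idx(i + t, H), j);
      out(i, j) = s;
    }
  }
  return out;
}

static inline int conv_out_size(int n, int p, int d, int k, int s) {
  return (n + 2 * p - d * (k - 1) - 1) / s + 1;
}

// cols: (k*k*C) x (Hout*Wout); row layout ki + kj*k + c*k*k (ki fastest),
// column layout i_out + j_out*Hout — both match R's column-major flattening.
// [[Rcpp::export]]
arma::mat cpp_im2col(const arma::cube& x, int k, int stride, int pad, int dil) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = conv_out_size(H, pad, dil, k, stride);
  const int Wo = conv_out_size(W, pad, dil, k, stride);
  if (Ho <= 0 || Wo <= 0) stop("non-positive convolution output size");
  arma::mat cols(k * k * C, Ho * Wo, arma::fill::zeros);
  for (int jo = 0; jo < Wo; ++jo) {
    for (int io = 0; io < Ho; ++io) {
      const int q = io + jo * Ho;
      for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < k; ++kj) {
          const int jj = jo * stride - pad + kj * dil;
          if (jj < 0 || jj >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            const int ii = io * stride - pad + ki * dil;
            if (ii < 0 || ii >= H) continue;
            cols(ki + kj * k + c * k * k, q) = x(ii, jj, c);
          }
        }
      }
    }
  }
  return cols;
}

// adjoint of im2col: scatter-add columns back into an H x W x C cube
// [[Rcpp::export]]
arma::cube cpp_col2im(const arma::mat& cols, int H, int W, int C,
                      int k, int stride, int pad, int dil) {
  const int Ho = conv_out_size(H, pad, dil, k, stride);
  const int Wo = conv_out_size(W, pad, dil, k, stride);
  if ((int)cols.n_cols != Ho * Wo || (int)cols.n_rows != k * k * C)
    stop("col2im: column matrix does not match target geometry");
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int jo = 0; jo < Wo; ++jo) {
    for (int io = 0; io < Ho; ++io) {
      const int q = io + jo * Ho;
      for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < k; ++kj) {
          const int jj = jo * stride - pad + kj * dil;
          if (jj < 0 || jj >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            const int ii = io * stride - pad + ki * dil;
            if (ii < 0 || ii >= H) continue;
            x(ii, jj, c) += cols(ki + kj * k + c * k * k, q);
          }
        }
      }
    }
  }
  return x;
}

// w: (k*k*Cin) x Cout, b: Cout
// [[Rcpp::export]]
arma::cube cpp_conv2d(const arma::cube& x, const arma::mat& w, const arma::vec& b,
                      int k, int stride, int pad, int dil) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = conv_out_size(H, pad, dil, k, stride);
  const int Wo = conv_out_size(W, pad, dil, k, stride);
  const int Cout = w.n_cols;
  arma::mat cols = cpp_im2col(x, k, stride, pad, dil);
  arma::mat yf = w.t() * cols;  // Cout x (Ho*Wo)
  arma::cube y(Ho, Wo, Cout);
  for (int c = 0; c < Cout; ++c) {
    y.slice(c) = arma::reshape(yf.row(c).t() + b(c), Ho, Wo);
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& w, const arma::cube& gy,
                    int k, int stride, int pad, int dil) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Cout = w.n_cols;
  const int Ho = gy.n_rows, Wo = gy.n_cols;
  arma::mat gyf(Cout, Ho * Wo);
  for (int c = 0; c < Cout; ++c) gyf.row(c) = arma::vectorise(gy.slice(c)).t();
  arma::mat cols = cpp_im2col(x, k, stride, pad, dil);
  arma::mat gw = cols * gyf.t();                  // (k*k*Cin) x Cout
  arma::vec gb = arma::sum(gyf, 1);
  arma::mat gcols = w * gyf;                      // (k*k*Cin) x (Ho*Wo)
  arma::cube gx = cpp_col2im(gcols, H, W, C, k, stride, pad, dil);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// transposed convolution; w stored in "conv orientation" (k*k*Cout) x Cin,
// i.e. as the weight of the ordinary convolution mapping the OUTPUT back to
// the input. Hout = (Hin-1)*stride - 2*pad + k + opad.
// [[Rcpp::export]]
arma::cube cpp_convt2d(const arma::cube& x, const arma::mat& w, const arma::vec& b,
                       int k, int stride, int pad, int opad) {
  const int Hx = x.n_rows, Wx = x.n_cols, Cin = x.n_slices;
  const int Cout = w.n_rows / (k * k);
  const int Hy = (Hx - 1) * stride - 2 * pad + k + opad;
  const int Wy = (Wx - 1) * stride - 2 * pad + k + opad;
  arma::mat xf(Cin, Hx * Wx);
  for (int c = 0; c < Cin; ++c) xf.row(c) = arma::vectorise(x.slice(c)).t();
  arma::mat cols = w * xf;  // (k*k*Cout) x (Hx*Wx)
  arma::cube y = cpp_col2im(cols, Hy, Wy, Cout, k, stride, pad, 1);
  for (int c = 0; c < Cout; ++c) y.slice(c) += b(c);
  return y;
}

// [[Rcpp::export]]
List cpp_convt2d_bwd(const arma::cube& x, const arma::mat& w, const arma::cube& gy,
                     int k, int stride, int pad) {
  const int Hx = x.n_rows, Wx = x.n_cols, Cin = x.n_slices;
  const int Cout = gy.n_slices;
  arma::mat xf(Cin, Hx * Wx);
  for (int c = 0; c < Cin; ++c) xf.row(c) = arma::vectorise(x.slice(c)).t();
  arma::mat gcols = cpp_im2col(gy, k, stride, pad, 1);  // (k*k*Cout) x (Hx*Wx)
  arma::mat gxf = w.t() * gcols;                        // Cin x (Hx*Wx)
  arma::cube gx(Hx, Wx, Cin);
  for (int c = 0; c < Cin; ++c) gx.slice(c) = arma::reshape(gxf.row(c).t(), Hx, Wx);
  arma::mat gw = gcols * xf.t();                        // (k*k*Cout) x Cin
  arma::vec gb(Cout);
  for (int c = 0; c < Cout; ++c) gb(c) = arma::accu(gy.slice(c));
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// max pooling, kernel k stride s, no padding; idx holds 1-based linear
// indices (R convention) of the winning input element.
// [[Rcpp::export]]
List cpp_maxpool(const arma::cube& x, int k, int s) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H - k) / s + 1, Wo = (W - k) / s + 1;
  if (Ho <= 0 || Wo <= 0) stop("pooling window larger than input");
  arma::cube y(Ho, Wo, C);
  IntegerVector idx(Ho * Wo * C);
  int q = 0;
  for (int c = 0; c < C; ++c) {
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        double best = -arma::datum::inf;
        int bi = 0;
        for (int kj = 0; kj < k; ++kj) {
          for (int ki = 0; ki < k; ++ki) {
            const int ii = io * s + ki, jj = jo * s + kj;
            const double v = x(ii, jj, c);
            if (v > best) { best = v; bi = ii + jj * H + c * H * W; }
          }
        }
        // note: y filled in (io, jo, c) order = column-major order of output
        y(io, jo, c) = best;
        idx[c * Ho * Wo + jo * Ho + io] = bi + 1;
        ++q;
      }
    }
  }
  (void)q;
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_bwd(const arma::cube& gy, const IntegerVector& idx,
                           int H, int W, int C) {
  arma::cube gx(H, W, C, arma::fill::zeros);
  const double* g = gy.memptr();
  double* p = gx.memptr();
  const int n = idx.size();
  for (int q = 0; q < n; ++q) p[idx[q] - 1] += g[q];
  return gx;
}
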