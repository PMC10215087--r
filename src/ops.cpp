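// Low-level tensor primitives for the RK segmentation network.
// Layout convention: a feature map is an arma::cube (H, W, C), matching an
// R array with dim = c(H, W, C). Convolution weights arrive flattened as
// (k*k*Cin) x Cout matrices (column-major over kh, kw, cin).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Build the im2col matrix: (k*k*Cin) x (H*W), zero padding (k-1)/2.
static mat im2col(const cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int p = (k - 1) / 2;
  mat M(k * k * C, H * W, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int row = kh + k * kw + k * k * c;
        const int dh = kh - p, dw = kw - p;
        for (int w = 0; w < W; ++w) {
          const int iw = w + dw;
          if (iw < 0 || iw >= W) continue;
          for (int h = 0; h < H; ++h) {
            const int ih = h + dh;
            if (ih < 0 || ih >= H) continue;
            M(row, h + H * w) = xc(ih, iw);
          }
        }
      }
    }
  }
  return M;
}

// Scatter-add of an im2col-shaped gradient back onto the input grid.
static cube col2im(const mat& M, const int k, const int H, const int W,
                   const int C) {
  const int p = (k - 1) / 2;
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& gc = gx.slice(c);
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int row = kh + k * kw + k * k * c;
        const int dh = kh - p, dw = kw - p;
        for (int w = 0; w < W; ++w) {
          const int iw = w + dw;
          if (iw < 0 || iw >= W) continue;
          for (int h = 0; h < H; ++h) {
            const int ih = h + dh;
            if (ih < 0 || ih >= H) continue;
            gc(ih, iw) += M(row, h + H * w);
          }
        }
      }
    }
  }
  return gx;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube& x, const arma::mat& wmat,
                          const arma::vec& bias, const int k) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = wmat.n_cols;
  mat M = im2col(x, k);               // (kkCin) x (HW)
  mat out = M.t() * wmat;             // (HW) x Cout
  out.each_row() += bias.t();
  cube y(H, W, Cout);
  std::memcpy(y.memptr(), out.memptr(), sizeof(double) * out.n_elem);
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& wmat,
                          const arma::cube& gy, const int k) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = gy.n_slices;
  mat G(const_cast<double*>(gy.memptr()), H * W, Cout, false, true);
  mat M = im2col(x, k);
  mat gw = M * G;                     // (kkCin) x Cout
  vec gb = sum(G, 0).t();
  mat gM = wmat * G.t();              // (kkCin) x (HW)
  cube gx = col2im(gM, k, H, W, Cin);
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// 2x2 max-pooling with stride 2; records the flat argmax per output cell.
// [[Rcpp::export]]
Rcpp::List cpp_maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  cube amax(Ho, Wo, C);  // flat indices stored as doubles (R-friendly)
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        const int h0 = 2 * h, w0 = 2 * w;
        double best = xc(h0, w0);
        uword bi = h0 + H * w0;
        const int hh[4] = {h0, h0 + 1, h0, h0 + 1};
        const int ww[4] = {w0, w0, w0 + 1, w0 + 1};
        for (int t = 1; t < 4; ++t) {
          const double v = xc(hh[t], ww[t]);
          if (v > best) { best = v; bi = hh[t] + H * ww[t]; }
        }
        y(h, w, c) = best;
        amax(h, w, c) = (double)bi;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("amax") = amax);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(const arma::cube& amax, const arma::cube& gy,
                            const int H, const int W) {
  const int C = gy.n_slices;
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& gc = gx.slice(c);
    const mat& gyc = gy.slice(c);
    const mat& ac = amax.slice(c);
    for (uword i = 0; i < gyc.n_elem; ++i) gc((uword)ac(i)) += gyc(i);
  }
  return gx;
}

// Bilinear x2 up-sampling with non-aligned corners: output cell oy samples
// the input at (oy + 0.5)/2 - 0.5, clamped at the border.
static inline void lin_coef(const int o, const int n, int& i0, int& i1,
                            double& w1) {
  double s = (o + 0.5) / 2.0 - 0.5;
  if (s < 0) s = 0;
  if (s > n - 1) s = n - 1;
  i0 = (int)std::floor(s);
  i1 = std::min(i0 + 1, n - 1);
  w1 = s - i0;
}

// [[Rcpp::export]]
arma::cube cpp_bilinear2x_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = 2 * H, Wo = 2 * W;
  cube y(Ho, Wo, C);
  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> fh(Ho), fw(Wo);
  for (int o = 0; o < Ho; ++o) lin_coef(o, H, h0[o], h1[o], fh[o]);
  for (int o = 0; o < Wo; ++o) lin_coef(o, W, w0[o], w1[o], fw[o]);
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    mat& yc = y.slice(c);
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        const double a = 1 - fh[oh], b = fh[oh];
        const double u = 1 - fw[ow], v = fw[ow];
        yc(oh, ow) = u * (a * xc(h0[oh], w0[ow]) + b * xc(h1[oh], w0[ow])) +
                     v * (a * xc(h0[oh], w1[ow]) + b * xc(h1[oh], w1[ow]));
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_bilinear2x_bwd(const arma::cube& gy, const int H, const int W) {
  const int C = gy.n_slices;
  const int Ho = 2 * H, Wo = 2 * W;
  cube gx(H, W, C, fill::zeros);
  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> fh(Ho), fw(Wo);
  for (int o = 0; o < Ho; ++o) lin_coef(o, H, h0[o], h1[o], fh[o]);
  for (int o = 0; o < Wo; ++o) lin_coef(o, W, w0[o], w1[o], fw[o]);
  for (int c = 0; c < C; ++c) {
    const mat& gyc = gy.slice(c);
    mat& gc = gx.slice(c);
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        const double g = gyc(oh, ow);
        const double a = 1 - fh[oh], b = fh[oh];
        const double u = 1 - fw[ow], v = fw[ow];
        gc(h0[oh], w0[ow]) += g * u * a;
        gc(h1[oh], w0[ow]) += g * u * b;
        gc(h0[oh], w1[ow]) += g * v * a;
        gc(h1[oh], w1[ow]) += g * v * b;
      }
    }
  }
  return gx;
}
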