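// Minimal CNN primitives: 2-D convolution (im2col + GEMM), nearest-neighbour
// upsampling, and replicate-padded image filtering. Tensors are arma::cube
// with dimensions (H, W, C); convolution weights are (kh*kw*Cin) x Cout
// matrices with patch elements ordered (di, dj, c) column-major, matching the
// R-side initialisers. im2col/col2im exploit that for stride 1 the source
// pixels of one output column form a contiguous run within an image column.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col(const cube& x, int kh, int kw, int stride, int pad,
                  int Hout, int Wout) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int K = kh * kw * C;
  const int N = Hout * Wout;
  mat cols(N, K, fill::zeros);      // row n = output pixel, col = patch elem
  const double* xmem = x.memptr();
  for (int c = 0; c < C; ++c) {
    const double* xs = xmem + (size_t)c * H * W;
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int krow = di + kh * (dj + kw * c);
        double* ccol = cols.colptr(krow);
        for (int j = 0; j < Wout; ++j) {
          const int src_j = j * stride + dj - pad;
          if (src_j < 0 || src_j >= W) continue;
          const double* xcol = xs + (size_t)src_j * H;
          double* cseg = ccol + (size_t)Hout * j;
          if (stride == 1) {
            // contiguous source run: src_i = i + di - pad for i in [i0, i1)
            int i0 = std::max(0, pad - di);
            int i1 = std::min(Hout, H - di + pad);
            if (i1 > i0)
              std::memcpy(cseg + i0, xcol + i0 + di - pad,
                          sizeof(double) * (size_t)(i1 - i0));
          } else {
            for (int i = 0; i < Hout; ++i) {
              const int src_i = i * stride + di - pad;
              if (src_i < 0 || src_i >= H) continue;
              cseg[i] = xcol[src_i];
            }
          }
        }
      }
    }
  }
  return cols;
}

static void col2im_acc(cube& gx, const mat& gcols, int kh, int kw,
                       int stride, int pad, int Hout, int Wout) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  double* xmem = gx.memptr();
  for (int c = 0; c < C; ++c) {
    double* xs = xmem + (size_t)c * H * W;
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int krow = di + kh * (dj + kw * c);
        const double* ccol = gcols.colptr(krow);
        for (int j = 0; j < Wout; ++j) {
          const int src_j = j * stride + dj - pad;
          if (src_j < 0 || src_j >= W) continue;
          double* xcol = xs + (size_t)src_j * H;
          const double* cseg = ccol + (size_t)Hout * j;
          if (stride == 1) {
            int i0 = std::max(0, pad - di);
            int i1 = std::min(Hout, H - di + pad);
            double* dst = xcol + i0 + di - pad;
            for (int i = i0; i < i1; ++i) dst[i - i0] += cseg[i];
          } else {
            for (int i = 0; i < Hout; ++i) {
              const int src_i = i * stride + di - pad;
              if (src_i < 0 || src_i >= H) continue;
              xcol[src_i] += cseg[i];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_forward(const arma::cube& x, const arma::mat& w,
                              const arma::vec& b, int kh, int kw,
                              int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols;
  const int Hout = (H + 2 * pad - kh) / stride + 1;
  const int Wout = (W + 2 * pad - kw) / stride + 1;
  const int Cout = w.n_cols;
  mat cols = im2col(x, kh, kw, stride, pad, Hout, Wout);
  mat out = cols * w;                // (Hout*Wout) x Cout
  out.each_row() += b.t();
  cube y(Hout, Wout, Cout);
  std::memcpy(y.memptr(), out.memptr(),
              sizeof(double) * (size_t)Hout * Wout * Cout);
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_backward(const arma::cube& x, const arma::mat& w,
                               const arma::cube& gout, int kh, int kw,
                               int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Hout = gout.n_rows, Wout = gout.n_cols, Cout = gout.n_slices;
  const mat G((double*)gout.memptr(), Hout * Wout, Cout, false, true);
  mat cols = im2col(x, kh, kw, stride, pad, Hout, Wout);
  mat gw = cols.t() * G;             // K x Cout
  vec gb = sum(G, 0).t();
  mat gcols = G * w.t();             // (Hout*Wout) x K
  cube gx(H, W, C, fill::zeros);
  col2im_acc(gx, gcols, kh, kw, stride, pad, Hout, Wout);
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// [[Rcpp::export]]
arma::cube cpp_upsample2(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c) {
    const double* xs = x.memptr() + (size_t)c * H * W;
    double* ys = y.memptr() + (size_t)c * 4 * H * W;
    for (int j = 0; j < W; ++j) {
      const double* xcol = xs + (size_t)j * H;
      double* y0 = ys + (size_t)(2 * j) * 2 * H;
      double* y1 = y0 + 2 * H;
      for (int i = 0; i < H; ++i) {
        const double v = xcol[i];
        y0[2 * i] = v; y0[2 * i + 1] = v;
        y1[2 * i] = v; y1[2 * i + 1] = v;
      }
    }
  }
  return y;
}

// Backward of upsample2 followed by a crop to (gH, gW): cells cropped away
// received zero gradient, so each source cell sums the surviving copies.
// [[Rcpp::export]]
arma::cube cpp_upsample2_backward(const arma::cube& g, int H, int W) {
  const int gH = g.n_rows, gW = g.n_cols, C = g.n_slices;
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < gW; ++j)
      for (int i = 0; i < gH; ++i)
        gx(i / 2, j / 2, c) += g(i, j, c);
  return gx;
}

// Same-size cross-correlation with replicate (edge-clamp) padding.
// [[Rcpp::export]]
arma::mat cpp_filter2_replicate(const arma::mat& img, const arma::mat& kernel) {
  const int H = img.n_rows, W = img.n_cols;
  const int kh = kernel.n_rows, kw = kernel.n_cols;
  const int ph = kh / 2, pw = kw / 2;
  mat out(H, W, fill::zeros);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int dj = 0; dj < kw; ++dj) {
        int sj = j + dj - pw;
        sj = sj < 0 ? 0 : (sj >= W ? W - 1 : sj);
        for (int di = 0; di < kh; ++di) {
          int si = i + di - ph;
          si = si < 0 ? 0 : (si >= H ? H - 1 : si);
          acc += kernel(di, dj) * img(si, sj);
        }
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Batched variants: a batch of activations is one contiguous R array with
// dims (H, W, C, B). Frames are aliased zero-copy; the im2col buffer is
// reused across the batch; gw/gb are summed over the batch.

// [[Rcpp::export]]
Rcpp::NumericVector cpp_convb_forward(Rcpp::NumericVector x4,
                                      const arma::mat& w, const arma::vec& b,
                                      int kh, int kw, int stride, int pad) {
  Rcpp::IntegerVector dm = x4.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], B = dm[3];
  const int Hout = (H + 2 * pad - kh) / stride + 1;
  const int Wout = (W + 2 * pad - kw) / stride + 1;
  const int Cout = w.n_cols;
  Rcpp::NumericVector y4((R_xlen_t)Hout * Wout * Cout * B);
  y4.attr("dim") = Rcpp::IntegerVector::create(Hout, Wout, Cout, B);
  double* ymem = REAL(y4);
  const double* xmem = REAL(x4);
  mat cols;
  for (int n = 0; n < B; ++n) {
    const cube x((double*)(xmem + (size_t)n * H * W * C), H, W, C,
                 false, true);
    cols = im2col(x, kh, kw, stride, pad, Hout, Wout);
    mat out(ymem + (size_t)n * Hout * Wout * Cout, Hout * Wout, Cout,
            false, true);
    out = cols * w;
    out.each_row() += b.t();
  }
  return y4;
}

// [[Rcpp::export]]
Rcpp::List cpp_convb_backward(Rcpp::NumericVector x4, const arma::mat& w,
                              Rcpp::NumericVector g4, int kh, int kw,
                              int stride, int pad, bool want_gx) {
  Rcpp::IntegerVector dm = x4.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], B = dm[3];
  Rcpp::IntegerVector gdm = g4.attr("dim");
  const int Hout = gdm[0], Wout = gdm[1], Cout = gdm[2];
  mat gw_sum(w.n_rows, w.n_cols, fill::zeros);
  vec gb_sum(w.n_cols, fill::zeros);
  Rcpp::NumericVector gx4(want_gx ? x4.size() : 0);
  if (want_gx) gx4.attr("dim") = dm;
  const double* xmem = REAL(x4);
  const double* gmem = REAL(g4);
  double* gxmem = want_gx ? REAL(gx4) : nullptr;
  mat cols, gcols;
  for (int n = 0; n < B; ++n) {
    const cube x((double*)(xmem + (size_t)n * H * W * C), H, W, C,
                 false, true);
    const mat G((double*)(gmem + (size_t)n * Hout * Wout * Cout),
                Hout * Wout, Cout, false, true);
    cols = im2col(x, kh, kw, stride, pad, Hout, Wout);
    gw_sum += cols.t() * G;
    gb_sum += sum(G, 0).t();
    if (want_gx) {
      gcols = G * w.t();
      cube gx(gxmem + (size_t)n * H * W * C, H, W, C, false, true);
      gx.zeros();
      col2im_acc(gx, gcols, kh, kw, stride, pad, Hout, Wout);
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx4,
                            Rcpp::Named("gw") = gw_sum,
                            Rcpp::Named("gb") = gb_sum);
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_upsampleb(Rcpp::NumericVector x4, int hout, int wout) {
  Rcpp::IntegerVector dm = x4.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], B = dm[3];
  Rcpp::NumericVector y4((R_xlen_t)hout * wout * C * B);
  y4.attr("dim") = Rcpp::IntegerVector::create(hout, wout, C, B);
  const double* xmem = REAL(x4);
  double* ymem = REAL(y4);
  for (int n = 0; n < B; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = xmem + (size_t)(n * C + c) * H * W;
      double* ys = ymem + (size_t)(n * C + c) * hout * wout;
      for (int j = 0; j < wout; ++j) {
        const double* xcol = xs + (size_t)(j / 2) * H;
        double* ycol = ys + (size_t)j * hout;
        for (int i = 0; i < hout; ++i) ycol[i] = xcol[i / 2];
      }
    }
  return y4;
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_upsampleb_backward(Rcpp::NumericVector g4,
                                           int H, int W) {
  Rcpp::IntegerVector dm = g4.attr("dim");
  const int gH = dm[0], gW = dm[1], C = dm[2], B = dm[3];
  Rcpp::NumericVector gx4((R_xlen_t)H * W * C * B);
  gx4.attr("dim") = Rcpp::IntegerVector::create(H, W, C, B);
  const double* gmem = REAL(g4);
  double* xmem = REAL(gx4);
  for (int n = 0; n < B; ++n)
    for (int c = 0; c < C; ++c) {
      const double* gs = gmem + (size_t)(n * C + c) * gH * gW;
      double* xs = xmem + (size_t)(n * C + c) * H * W;
      for (int j = 0; j < gW; ++j) {
        const double* gcol = gs + (size_t)j * gH;
        double* xcol = xs + (size_t)(j / 2) * H;
        for (int i = 0; i < gH; ++i) xcol[i / 2] += gcol[i];
      }
    }
  return gx4;
}
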