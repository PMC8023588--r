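// Shared single-precision CNN primitives for the C++ training loops.
#pragma once
#include <RcppArmadillo.h>
#include <cstring>

namespace octsubset_nnf {
using namespace arma;


inline void im2col_f(const fcube& x, int stride, fmat& cols, int Hout, int Wout) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int kh = 3, kw = 3, pad = 1;
  cols.zeros(Hout * Wout, kh * kw * C);
  for (int c = 0; c < C; ++c) {
    const float* xs = x.memptr() + (size_t)c * H * W;
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int krow = di + kh * (dj + kw * c);
        float* ccol = cols.colptr(krow);
        for (int j = 0; j < Wout; ++j) {
          const int src_j = j * stride + dj - pad;
          if (src_j < 0 || src_j >= W) continue;
          const float* xcol = xs + (size_t)src_j * H;
          float* cseg = ccol + (size_t)Hout * j;
          if (stride == 1) {
            int i0 = std::max(0, pad - di);
            int i1 = std::min(Hout, H - di + pad);
            if (i1 > i0)
              std::memcpy(cseg + i0, xcol + i0 + di - pad,
                          sizeof(float) * (size_t)(i1 - i0));
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
}

inline void col2im_acc_f(fcube& gx, const fmat& gcols, int stride,
                  int Hout, int Wout) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  const int kh = 3, kw = 3, pad = 1;
  for (int c = 0; c < C; ++c) {
    float* xs = gx.memptr() + (size_t)c * H * W;
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int krow = di + kh * (dj + kw * c);
        const float* ccol = gcols.colptr(krow);
        for (int j = 0; j < Wout; ++j) {
          const int src_j = j * stride + dj - pad;
          if (src_j < 0 || src_j >= W) continue;
          float* xcol = xs + (size_t)src_j * H;
          const float* cseg = ccol + (size_t)Hout * j;
          if (stride == 1) {
            int i0 = std::max(0, pad - di);
            int i1 = std::min(Hout, H - di + pad);
            float* dst = xcol + i0 + di - pad;
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

inline void upsample2_crop_f(const fcube& x, fcube& y, int hout, int wout) {
  const int H = x.n_rows;
  const int C = x.n_slices;
  y.set_size(hout, wout, C);
  for (int c = 0; c < C; ++c) {
    const float* xs = x.memptr() + (size_t)c * H * x.n_cols;
    float* ys = y.memptr() + (size_t)c * hout * wout;
    for (int j = 0; j < wout; ++j) {
      const float* xcol = xs + (size_t)(j / 2) * H;
      float* ycol = ys + (size_t)j * hout;
      for (int i = 0; i < hout; ++i) ycol[i] = xcol[i / 2];
    }
  }
}

inline void upsample2_back_f(const fcube& g, fcube& gx, int H, int W) {
  const int gH = g.n_rows, gW = g.n_cols, C = g.n_slices;
  gx.zeros(H, W, C);
  for (int c = 0; c < C; ++c) {
    const float* gs = g.memptr() + (size_t)c * gH * gW;
    float* xs = gx.memptr() + (size_t)c * H * W;
    for (int j = 0; j < gW; ++j) {
      const float* gcol = gs + (size_t)j * gH;
      float* xcol = xs + (size_t)(j / 2) * H;
      for (int i = 0; i < gH; ++i) xcol[i / 2] += gcol[i];
    }
  }
}

struct ConvLayer {
  fmat W;        // (9*Cin) x Cout
  fvec b;
  int stride;
  // Adam state
  fmat mW, vW;
  fvec mb, vb;
  // grad accumulators
  fmat gW;
  fvec gb;
};

inline void conv_fwd(const ConvLayer& L, const fcube& x, fcube& y, fmat& cols) {
  const int H = x.n_rows, W = x.n_cols;
  const int Hout = (H + 2 - 3) / L.stride + 1;
  const int Wout = (W + 2 - 3) / L.stride + 1;
  const int Cout = L.W.n_cols;
  im2col_f(x, L.stride, cols, Hout, Wout);
  fmat out = cols * L.W;
  out.each_row() += L.b.t();
  y.set_size(Hout, Wout, Cout);
  std::memcpy(y.memptr(), out.memptr(),
              sizeof(float) * (size_t)Hout * Wout * Cout);
}

// gout given; accumulates gW/gb; writes gx unless want_gx is false
inline void conv_bwd(ConvLayer& L, const fcube& x, const fcube& gout, fcube& gx,
              fmat& cols, bool want_gx) {
  const int Hout = gout.n_rows, Wout = gout.n_cols, Cout = gout.n_slices;
  const fmat G((float*)gout.memptr(), Hout * Wout, Cout, false, true);
  im2col_f(x, L.stride, cols, Hout, Wout);
  L.gW += cols.t() * G;
  L.gb += sum(G, 0).t();
  if (want_gx) {
    fmat gcols = G * L.W.t();
    gx.zeros(x.n_rows, x.n_cols, x.n_slices);
    col2im_acc_f(gx, gcols, L.stride, Hout, Wout);
  }
}

inline void relu_ip(fcube& a) {
  float* p = a.memptr();
  const size_t n = a.n_elem;
  for (size_t i = 0; i < n; ++i) if (p[i] < 0) p[i] = 0;
}

}  // namespace octsubset_nnf
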