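// Full training loop of the compact U-net segmenter in single precision:
// per-stage stride-1 conv (skip source) + stride-2 down conv, mid conv,
// nearest-upsample + conv + skip concat + conv decoder stages, sigmoid head,
// weighted binary cross-entropy, Adam, optional early stopping on a
// validation set. Mirrors the R reference (unet_forward / unet_backward).
// Weight initialisation and epoch permutations come from the caller so the
// R RNG fully determines the run.

#include "nn_float.h"
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using namespace octsubset_nnf;

namespace {

struct UnetCache {
  std::vector<fcube> encA_in, skip, encB_out;   // d each
  fcube mid_out;
  std::vector<fcube> up, u, cat, decM_out;      // d each (0-based stage)
};

struct UnetNet {
  int d;
  std::vector<int> w;            // stage widths
  std::vector<ConvLayer>* L;
  // layer indices
  int encA(int k) const { return 2 * k; }           // k 0-based
  int encB(int k) const { return 2 * k + 1; }
  int mid() const { return 2 * d; }
  int decU(int k) const { return 2 * d + 1 + 2 * (d - 1 - k); }
  int decM(int k) const { return 2 * d + 1 + 2 * (d - 1 - k) + 1; }
  int out() const { return 4 * d + 1; }
};

void unet_forward_f(const UnetNet& net, const fcube& x, UnetCache& cc,
                    fcube& prob, fmat& cols) {
  const int d = net.d;
  std::vector<ConvLayer>& L = *net.L;
  cc.encA_in.resize(d); cc.skip.resize(d); cc.encB_out.resize(d);
  cc.up.resize(d); cc.u.resize(d); cc.cat.resize(d); cc.decM_out.resize(d);
  fcube a = x, t;
  for (int k = 0; k < d; ++k) {
    cc.encA_in[k] = a;
    conv_fwd(L[net.encA(k)], a, t, cols);
    relu_ip(t);
    cc.skip[k] = t;
    conv_fwd(L[net.encB(k)], cc.skip[k], a, cols);
    relu_ip(a);
    cc.encB_out[k] = a;
  }
  conv_fwd(L[net.mid()], a, t, cols);
  relu_ip(t);
  cc.mid_out = t;
  a = t;
  for (int k = d - 1; k >= 0; --k) {
    const fcube& sk = cc.skip[k];
    upsample2_crop_f(a, cc.up[k], sk.n_rows, sk.n_cols);
    conv_fwd(L[net.decU(k)], cc.up[k], cc.u[k], cols);
    relu_ip(cc.u[k]);
    const fcube& u = cc.u[k];
    fcube cat(sk.n_rows, sk.n_cols, sk.n_slices + u.n_slices);
    std::memcpy(cat.memptr(), sk.memptr(), sizeof(float) * sk.n_elem);
    std::memcpy(cat.memptr() + sk.n_elem, u.memptr(),
                sizeof(float) * u.n_elem);
    cc.cat[k] = cat;
    conv_fwd(L[net.decM(k)], cat, a, cols);
    relu_ip(a);
    cc.decM_out[k] = a;
  }
  conv_fwd(L[net.out()], a, prob, cols);
  float* p = prob.memptr();
  for (size_t i = 0; i < prob.n_elem; ++i)
    p[i] = 1.0f / (1.0f + std::exp(-p[i]));
}

// Forward without caches: skips must live somewhere — simplest correct
// variant keeps a local vector.
void unet_predict_f(const UnetNet& net, const fcube& x, fcube& prob,
                    fmat& cols) {
  const int d = net.d;
  std::vector<ConvLayer>& L = *net.L;
  std::vector<fcube> skips(d);
  fcube a = x, t;
  for (int k = 0; k < d; ++k) {
    conv_fwd(L[net.encA(k)], a, t, cols);
    relu_ip(t);
    skips[k] = t;
    conv_fwd(L[net.encB(k)], skips[k], a, cols);
    relu_ip(a);
  }
  conv_fwd(L[net.mid()], a, t, cols);
  relu_ip(t);
  a = t;
  for (int k = d - 1; k >= 0; --k) {
    const fcube& sk = skips[k];
    fcube up;
    upsample2_crop_f(a, up, sk.n_rows, sk.n_cols);
    fcube u;
    conv_fwd(L[net.decU(k)], up, u, cols);
    relu_ip(u);
    fcube cat(sk.n_rows, sk.n_cols, sk.n_slices + u.n_slices);
    std::memcpy(cat.memptr(), sk.memptr(), sizeof(float) * sk.n_elem);
    std::memcpy(cat.memptr() + sk.n_elem, u.memptr(),
                sizeof(float) * u.n_elem);
    conv_fwd(L[net.decM(k)], cat, a, cols);
    relu_ip(a);
  }
  conv_fwd(L[net.out()], a, prob, cols);
  float* p = prob.memptr();
  for (size_t i = 0; i < prob.n_elem; ++i)
    p[i] = 1.0f / (1.0f + std::exp(-p[i]));
}

inline void relu_mask_ip(fcube& g, const fcube& act) {
  float* gp = g.memptr();
  const float* ap = act.memptr();
  for (size_t i = 0; i < g.n_elem; ++i) if (ap[i] <= 0) gp[i] = 0;
}

double wbce_f(const fcube& prob, const float* y, float wc, float wo) {
  const float eps = 1e-7f;
  const float* p = prob.memptr();
  double loss = 0.0;
  for (size_t i = 0; i < prob.n_elem; ++i) {
    const float pc = std::min(std::max(p[i], eps), 1.0f - eps);
    loss -= y[i] > 0.5f ? wc * std::log(pc) : wo * std::log(1.0f - pc);
  }
  return loss / prob.n_elem;
}

}  // namespace

// x4/y4: (H, W, 1, N) images and binary masks; xv4/yv4: validation set (may
// have 0 frames when patience == 0); init: unet_build() layer list; perms:
// max_epochs x N 1-based orders. patience == 0 runs exactly max_epochs with
// no validation tracking. Returns the best-epoch weights (early-stopping
// mode) or the final ones.
// [[Rcpp::export]]
Rcpp::List cpp_unet_train(Rcpp::NumericVector x4, Rcpp::NumericVector y4,
                          Rcpp::NumericVector xv4, Rcpp::NumericVector yv4,
                          Rcpp::List init, Rcpp::IntegerVector widths,
                          Rcpp::IntegerMatrix perms, int batch, double lr,
                          double w_calc, double w_other, int patience,
                          double beta1 = 0.9, double beta2 = 0.999,
                          double adam_eps = 1e-8) {
  Rcpp::IntegerVector dm = x4.attr("dim");
  const int H = dm[0], Wd = dm[1], N = dm[3];
  int NV = 0;
  if (xv4.size() > 0) {
    Rcpp::IntegerVector dv = xv4.attr("dim");
    NV = dv[3];
  }
  const int d = widths.size();
  const int max_epochs = perms.nrow();
  const float wc = (float)w_calc, wo = (float)w_other;
  const float npix = (float)((size_t)H * Wd);

  auto to_f = [H, Wd](const double* src, fcube& dst) {
    dst.set_size(H, Wd, 1);
    float* p = dst.memptr();
    for (size_t k = 0; k < (size_t)H * Wd; ++k) p[k] = (float)src[k];
  };
  std::vector<fcube> xs(N), ys(N), xvs(NV), yvs(NV);
  for (int i = 0; i < N; ++i) {
    to_f(REAL(x4) + (size_t)i * H * Wd, xs[i]);
    to_f(REAL(y4) + (size_t)i * H * Wd, ys[i]);
  }
  for (int i = 0; i < NV; ++i) {
    to_f(REAL(xv4) + (size_t)i * H * Wd, xvs[i]);
    to_f(REAL(yv4) + (size_t)i * H * Wd, yvs[i]);
  }

  const int n_layers = init.size();
  std::vector<ConvLayer> L(n_layers);
  for (int li = 0; li < n_layers; ++li) {
    Rcpp::List lay = init[li];
    L[li].W = conv_to<fmat>::from(Rcpp::as<mat>(lay["w"]));
    L[li].b = conv_to<fvec>::from(Rcpp::as<vec>(lay["b"]));
    L[li].stride = Rcpp::as<int>(lay["stride"]);
    L[li].mW.zeros(size(L[li].W)); L[li].vW.zeros(size(L[li].W));
    L[li].mb.zeros(L[li].b.n_elem); L[li].vb.zeros(L[li].b.n_elem);
    L[li].gW.zeros(size(L[li].W)); L[li].gb.zeros(L[li].b.n_elem);
  }
  UnetNet net;
  net.d = d;
  net.w.assign(widths.begin(), widths.end());
  net.L = &L;

  std::vector<double> train_loss, val_loss;
  std::vector<fmat> bestW(n_layers);
  std::vector<fvec> bestB(n_layers);
  double best_val = std::numeric_limits<double>::infinity();
  int best_epoch = 0, bad = 0, stopped = 0;
  long adam_t = 0;

  std::vector<UnetCache> caches(batch);
  std::vector<fcube> probs(batch);
  std::vector<int> fids(batch);
  fmat cols;
  fcube g, g2, gu, gup, prob;

  for (int ep = 0; ep < max_epochs; ++ep) {
    double ep_loss = 0.0;
    for (int b0 = 0; b0 < N; b0 += batch) {
      const int B = std::min(batch, N - b0);
      for (int li = 0; li < n_layers; ++li) {
        L[li].gW.zeros(); L[li].gb.zeros();
      }
      for (int bi = 0; bi < B; ++bi) {
        const int fi = perms(ep, b0 + bi) - 1;
        fids[bi] = fi;
        unet_forward_f(net, xs[fi], caches[bi], probs[bi], cols);
        ep_loss += wbce_f(probs[bi], ys[fi].memptr(), wc, wo);
      }
      if (!std::isfinite(ep_loss))
        Rcpp::stop("non-finite training loss at epoch %d", ep + 1);
      for (int bi = 0; bi < B; ++bi) {
        UnetCache& cc = caches[bi];
        const float* y = ys[fids[bi]].memptr();
        // d(loss)/d(logit): (-wc*y*(1-p) + wo*(1-y)*p) / (npix * B)
        g = probs[bi];
        float* gp = g.memptr();
        for (size_t i = 0; i < g.n_elem; ++i) {
          const float p = gp[i];
          gp[i] = (y[i] > 0.5f ? -wc * (1.0f - p) : wo * p) / (npix * B);
        }
        conv_bwd(L[net.out()], cc.decM_out[0], g, g2, cols, true);
        g = g2;
        for (int k = 0; k < d; ++k) {     // reverse decoder order
          relu_mask_ip(g, cc.decM_out[k]);
          conv_bwd(L[net.decM(k)], cc.cat[k], g, g2, cols, true);
          // split channel groups: first w[k] to the skip, rest to decU
          const int wk = net.w[k];
          const fcube& gcat = g2;
          fcube gskip(gcat.n_rows, gcat.n_cols, wk);
          gu.set_size(gcat.n_rows, gcat.n_cols, wk);
          std::memcpy(gskip.memptr(), gcat.memptr(),
                      sizeof(float) * gskip.n_elem);
          std::memcpy(gu.memptr(), gcat.memptr() + gskip.n_elem,
                      sizeof(float) * gu.n_elem);
          cc.cat[k] = gskip;              // reuse slot to carry skip grad
          relu_mask_ip(gu, cc.u[k]);
          conv_bwd(L[net.decU(k)], cc.up[k], gu, gup, cols, true);
          const fcube& below = (k == d - 1) ? cc.mid_out : cc.decM_out[k + 1];
          upsample2_back_f(gup, g, below.n_rows, below.n_cols);
        }
        relu_mask_ip(g, cc.mid_out);
        conv_bwd(L[net.mid()], cc.encB_out[d - 1], g, g2, cols, true);
        g = g2;
        for (int k = d - 1; k >= 0; --k) {
          relu_mask_ip(g, cc.encB_out[k]);
          conv_bwd(L[net.encB(k)], cc.skip[k], g, g2, cols, true);
          g = g2 + cc.cat[k];             // add the skip-path gradient
          relu_mask_ip(g, cc.skip[k]);
          conv_bwd(L[net.encA(k)], cc.encA_in[k], g, g2, cols, k > 0);
          g = g2;
        }
      }
      adam_t += 1;
      const float c1 = 1.0f - std::pow((float)beta1, (float)adam_t);
      const float c2 = 1.0f - std::pow((float)beta2, (float)adam_t);
      for (int li = 0; li < n_layers; ++li) {
        ConvLayer& ly = L[li];
        ly.mW = (float)beta1 * ly.mW + (1.0f - (float)beta1) * ly.gW;
        ly.vW = (float)beta2 * ly.vW + (1.0f - (float)beta2) * square(ly.gW);
        ly.mb = (float)beta1 * ly.mb + (1.0f - (float)beta1) * ly.gb;
        ly.vb = (float)beta2 * ly.vb + (1.0f - (float)beta2) * square(ly.gb);
        ly.W -= (float)lr * (ly.mW / c1) / (sqrt(ly.vW / c2) + (float)adam_eps);
        ly.b -= (float)lr * (ly.mb / c1) / (sqrt(ly.vb / c2) + (float)adam_eps);
      }
    }
    train_loss.push_back(ep_loss / N);
    stopped = ep + 1;
    if (patience > 0) {
      double vl = 0.0;
      for (int i = 0; i < NV; ++i) {
        unet_predict_f(net, xvs[i], prob, cols);
        vl += wbce_f(prob, yvs[i].memptr(), wc, wo);
      }
      vl /= NV;
      val_loss.push_back(vl);
      if (vl < best_val) {
        best_val = vl;
        best_epoch = ep + 1;
        for (int li = 0; li < n_layers; ++li) {
          bestW[li] = L[li].W;
          bestB[li] = L[li].b;
        }
        bad = 0;
      } else if (++bad >= patience) break;
    }
    Rcpp::checkUserInterrupt();
  }
  if (patience > 0 && best_epoch > 0)
    for (int li = 0; li < n_layers; ++li) {
      L[li].W = bestW[li];
      L[li].b = bestB[li];
    }

  Rcpp::List out_layers(n_layers);
  for (int li = 0; li < n_layers; ++li)
    out_layers[li] = Rcpp::List::create(
      Rcpp::Named("w") = conv_to<mat>::from(L[li].W),
      Rcpp::Named("b") = conv_to<vec>::from(L[li].b),
      Rcpp::Named("stride") = L[li].stride);
  return Rcpp::List::create(
    Rcpp::Named("layers") = out_layers,
    Rcpp::Named("train_loss") = train_loss,
    Rcpp::Named("val_loss") = val_loss,
    Rcpp::Named("stopped_epoch") = stopped,
    Rcpp::Named("best_epoch") = patience > 0 ? best_epoch : stopped);
}
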