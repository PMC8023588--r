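// Full training loop of the compact autoencoder in single precision:
// strided-conv encoder, nearest-upsample decoder, half-resolution 1-channel
// projection, sigmoid output, MSE loss, Adam. Mirrors the R reference
// implementation (ae_forward / ae_backward / nn_adam_step) layer for layer;
// weight initialisation and epoch permutations are supplied by the caller so
// the R RNG fully determines the run.

#include "nn_float.h"
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

using namespace octsubset_nnf;


// x4: (H, W, 1, N) double array of frames; init: list of layers (w, b) in
// order enc1..encd, decd..dec2, out; perms: epochs x n 1-based frame order.
// [[Rcpp::export]]
Rcpp::List cpp_ae_train(Rcpp::NumericVector x4, Rcpp::List init,
                        Rcpp::IntegerVector widths,
                        Rcpp::IntegerMatrix perms, int batch,
                        double lr, double beta1 = 0.9, double beta2 = 0.999,
                        double adam_eps = 1e-8) {
  Rcpp::IntegerVector dm = x4.attr("dim");
  const int H = dm[0], Wd = dm[1], N = dm[3];
  const int d = widths.size();
  const int n_layers = init.size();   // 2 * d (enc + dec) with out = last
  const int epochs = perms.nrow();

  // frames to float
  std::vector<fcube> frames(N);
  const double* xmem = REAL(x4);
  for (int i = 0; i < N; ++i) {
    frames[i].set_size(H, Wd, 1);
    const double* src = xmem + (size_t)i * H * Wd;
    float* dst = frames[i].memptr();
    for (size_t k = 0; k < (size_t)H * Wd; ++k) dst[k] = (float)src[k];
  }

  // layers
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

  // spatial sizes per stage
  std::vector<int> Hs(d + 1), Ws(d + 1);
  Hs[0] = H; Ws[0] = Wd;
  for (int k = 1; k <= d; ++k) {
    Hs[k] = (Hs[k - 1] - 1) / 2 + 1;
    Ws[k] = (Ws[k - 1] - 1) / 2 + 1;
  }

  const float npix = (float)((size_t)H * Wd);
  std::vector<double> epoch_loss(epochs, 0.0);
  long adam_t = 0;

  // caches per frame-in-batch
  std::vector<std::vector<fcube>> enc_in(batch, std::vector<fcube>(d));
  std::vector<std::vector<fcube>> enc_out(batch, std::vector<fcube>(d));
  std::vector<std::vector<fcube>> dec_in(batch, std::vector<fcube>(d - 1));
  std::vector<std::vector<fcube>> dec_out(batch, std::vector<fcube>(d - 1));
  std::vector<fcube> out_in(batch), z_half(batch), recon(batch);
  fmat cols;
  fcube tmp, g, g2;

  for (int ep = 0; ep < epochs; ++ep) {
    double ep_loss = 0.0;
    for (int b0 = 0; b0 < N; b0 += batch) {
      const int B = std::min(batch, N - b0);
      for (int li = 0; li < n_layers; ++li) {
        L[li].gW.zeros(); L[li].gb.zeros();
      }
      double batch_loss = 0.0;
      for (int bi = 0; bi < B; ++bi) {
        const int fi = perms(ep, b0 + bi) - 1;
        // forward
        const fcube* a = &frames[fi];
        for (int k = 0; k < d; ++k) {
          enc_in[bi][k] = *a;
          conv_fwd(L[k], enc_in[bi][k], enc_out[bi][k], cols);
          relu_ip(enc_out[bi][k]);
          a = &enc_out[bi][k];
        }
        for (int k = d; k >= 2; --k) {   // layer index d + (d - k)
          const int li = d + (d - k);
          upsample2_crop_f(*a, tmp, Hs[k - 1], Ws[k - 1]);
          dec_in[bi][d - k] = tmp;
          conv_fwd(L[li], dec_in[bi][d - k], dec_out[bi][d - k], cols);
          relu_ip(dec_out[bi][d - k]);
          a = &dec_out[bi][d - k];
        }
        out_in[bi] = *a;
        conv_fwd(L[n_layers - 1], out_in[bi], z_half[bi], cols);
        upsample2_crop_f(z_half[bi], recon[bi], H, Wd);
        // sigmoid + loss + output grad (pre-sigmoid, at full res)
        float* r = recon[bi].memptr();
        const float* x0 = frames[fi].memptr();
        double loss = 0.0;
        for (size_t k = 0; k < (size_t)H * Wd; ++k) {
          const float s = 1.0f / (1.0f + std::exp(-r[k]));
          const float diff = s - x0[k];
          loss += (double)diff * diff;
          r[k] = 2.0f * diff / (npix * B) * s * (1.0f - s);
        }
        batch_loss += loss / npix;
      }
      ep_loss += batch_loss;
      if (!std::isfinite(batch_loss))
        Rcpp::stop("non-finite autoencoder loss at epoch %d", ep + 1);
      // backward
      for (int bi = 0; bi < B; ++bi) {
        upsample2_back_f(recon[bi], g, Hs[1], Ws[1]);
        conv_bwd(L[n_layers - 1], out_in[bi], g, g2, cols, true);
        g = g2;
        for (int k = 2; k <= d; ++k) {   // reverse decoder
          const int li = d + (d - k);
          fcube& ro = dec_out[bi][d - k];
          float* gp = g.memptr();
          const float* rp = ro.memptr();
          for (size_t t = 0; t < g.n_elem; ++t) if (rp[t] <= 0) gp[t] = 0;
          conv_bwd(L[li], dec_in[bi][d - k], g, g2, cols, true);
          upsample2_back_f(g2, g, Hs[k], Ws[k]);
        }
        for (int k = d - 1; k >= 0; --k) {
          fcube& ro = enc_out[bi][k];
          float* gp = g.memptr();
          const float* rp = ro.memptr();
          for (size_t t = 0; t < g.n_elem; ++t) if (rp[t] <= 0) gp[t] = 0;
          conv_bwd(L[k], enc_in[bi][k], g, g2, cols, k > 0);
          g = g2;
        }
      }
      // Adam step
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
    epoch_loss[ep] = ep_loss / N;   // mean per-frame MSE over the epoch
    Rcpp::checkUserInterrupt();
  }

  Rcpp::List out_layers(n_layers);
  for (int li = 0; li < n_layers; ++li) {
    out_layers[li] = Rcpp::List::create(
      Rcpp::Named("w") = conv_to<mat>::from(L[li].W),
      Rcpp::Named("b") = conv_to<vec>::from(L[li].b),
      Rcpp::Named("stride") = L[li].stride);
  }
  return Rcpp::List::create(Rcpp::Named("layers") = out_layers,
                            Rcpp::Named("epoch_loss") = epoch_loss);
}
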