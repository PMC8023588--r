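# Compact convolutional architectures built on the nn engine. All forward /
# backward passes are batched: a batch of activations is a 4-D array
# (H, W, C, B). Input frames are single-channel matrices.
#
# Autoencoder (frame selection): strided-conv encoder, mirrored
# nearest-upsample decoder, no skip connections so the bottleneck carries all
# information. The 1-channel projection sits at half resolution and the final
# mirrored upsampling stage maps it to input size; on speckle-reduced
# (Gaussian-filtered) frames the half-resolution representation is essentially
# lossless and it halves the cost of the two most expensive layers.
#
# U-net segmenter: per-stage stride-1 conv (skip source) + stride-2 conv down,
# single mid conv, nearest-upsample + conv + skip concat + conv per decoder
# stage, sigmoid 1-channel head at full resolution.

nn_batchify <- function(frames) {
  if (is.matrix(frames)) frames <- list(frames)
  d <- dim(frames[[1L]])
  x <- array(unlist(frames, use.names = FALSE), c(d[1], d[2], 1L, length(frames)))
  x
}

nnb_conv_fwd <- function(layer, x) {
  cpp_convb_forward(x, layer$w, layer$b, layer$kh, layer$kw, layer$stride, 1L)
}

nnb_conv_bwd <- function(layer, x, g, want_gx = TRUE) {
  cpp_convb_backward(x, layer$w, g, layer$kh, layer$kw, layer$stride, 1L,
                     want_gx)
}

nnb_relu <- function(x) {
  x[x < 0] <- 0
  x
}

nnb_concat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a
  y[, , da[3] + seq_len(db[3]), ] <- b
  y
}

ae_build <- function(widths = c(8L, 16L, 32L, 64L)) {
  widths <- as.integer(widths)
  stopifnot(length(widths) >= 2L, all(widths >= 1L))
  d <- length(widths)
  cins <- c(1L, widths[-d])
  layers <- list()
  for (k in seq_len(d))
    layers[[paste0("enc", k)]] <- nn_conv_init(cins[k], widths[k], stride = 2L)
  for (k in seq(d, 2L))
    layers[[paste0("dec", k)]] <- nn_conv_init(widths[k], widths[k - 1L])
  layers[["out"]] <- nn_conv_init(widths[1L], 1L)
  structure(list(layers = layers, widths = widths, depth = d),
            class = "oct_autoencoder")
}

# x: (H, W, 1, B) batch array. Returns reconstructions (H, W, 1, B),
# bottleneck activations and, optionally, the cache for ae_backward().
ae_forward <- function(model, x, keep_cache = FALSE) {
  d <- model$depth
  L <- model$layers
  a <- x
  sizes <- vector("list", d + 1L)
  sizes[[1L]] <- dim(a)[1:2]
  cache <- list(conv_in = list(), relu_out = list(), pre_up_dim = list())
  for (k in seq_len(d)) {
    nm <- paste0("enc", k)
    cache$conv_in[[nm]] <- a
    a <- nnb_relu(nnb_conv_fwd(L[[nm]], a))
    cache$relu_out[[nm]] <- a
    sizes[[k + 1L]] <- dim(a)[1:2]
  }
  bottleneck <- a
  for (k in seq(d, 2L)) {
    nm <- paste0("dec", k)
    cache$pre_up_dim[[nm]] <- dim(a)[1:2]
    up <- cpp_upsampleb(a, sizes[[k]][1], sizes[[k]][2])
    cache$conv_in[[nm]] <- up
    a <- nnb_relu(nnb_conv_fwd(L[[nm]], up))
    cache$relu_out[[nm]] <- a
  }
  cache$conv_in[["out"]] <- a
  z_half <- nnb_conv_fwd(L[["out"]], a)
  z_full <- cpp_upsampleb(z_half, sizes[[1L]][1], sizes[[1L]][2])
  recon <- nn_sigmoid(z_full)
  cache$z_half_dim <- dim(z_half)[1:2]
  res <- list(recon = recon, bottleneck = bottleneck)
  if (keep_cache) res$cache <- cache
  res
}

# Backward from d(loss)/d(pre-sigmoid full-resolution logits) `gz`
# (H, W, 1, B). Returns per-layer weight/bias gradients (summed over batch).
ae_backward <- function(model, cache, gz) {
  d <- model$depth
  L <- model$layers
  grads <- list()
  g <- cpp_upsampleb_backward(gz, cache$z_half_dim[1], cache$z_half_dim[2])
  bw <- nnb_conv_bwd(L[["out"]], cache$conv_in[["out"]], g)
  grads[["out"]] <- list(gw = bw$gw, gb = bw$gb)
  g <- bw$gx
  for (k in seq(2L, d)) {          # reverse of decoder order d..2
    nm <- paste0("dec", k)
    g <- g * (cache$relu_out[[nm]] > 0)
    bw <- nnb_conv_bwd(L[[nm]], cache$conv_in[[nm]], g)
    grads[[nm]] <- list(gw = bw$gw, gb = bw$gb)
    pud <- cache$pre_up_dim[[nm]]
    g <- cpp_upsampleb_backward(bw$gx, pud[1], pud[2])
  }
  for (k in seq(d, 1L)) {
    nm <- paste0("enc", k)
    g <- g * (cache$relu_out[[nm]] > 0)
    bw <- nnb_conv_bwd(L[[nm]], cache$conv_in[[nm]], g, want_gx = k > 1L)
    grads[[nm]] <- list(gw = bw$gw, gb = bw$gb)
    g <- bw$gx
  }
  grads[names(model$layers)]
}

unet_build <- function(widths = c(8L, 16L, 32L)) {
  widths <- as.integer(widths)
  stopifnot(length(widths) >= 1L, all(widths >= 1L))
  d <- length(widths)
  cins <- c(1L, widths[-d])
  layers <- list()
  for (k in seq_len(d)) {
    layers[[paste0("encA", k)]] <- nn_conv_init(cins[k], widths[k])
    layers[[paste0("encB", k)]] <- nn_conv_init(widths[k], widths[k], stride = 2L)
  }
  layers[["mid"]] <- nn_conv_init(widths[d], 2L * widths[d])
  prev <- 2L * widths[d]
  for (k in seq(d, 1L)) {
    layers[[paste0("decU", k)]] <- nn_conv_init(prev, widths[k])
    layers[[paste0("decM", k)]] <- nn_conv_init(2L * widths[k], widths[k])
    prev <- widths[k]
  }
  layers[["out"]] <- nn_conv_init(widths[1L], 1L)
  structure(list(layers = layers, widths = widths, depth = d),
            class = "oct_unet")
}

# x: (H, W, 1, B); returns pixel probabilities (H, W, 1, B).
unet_forward <- function(model, x, keep_cache = FALSE) {
  d <- model$depth
  L <- model$layers
  a <- x
  cc <- list(conv_in = list(), relu_out = list(), pre_up_dim = list())
  skips <- vector("list", d)
  for (k in seq_len(d)) {
    nmA <- paste0("encA", k); nmB <- paste0("encB", k)
    cc$conv_in[[nmA]] <- a
    sk <- nnb_relu(nnb_conv_fwd(L[[nmA]], a))
    cc$relu_out[[nmA]] <- sk
    skips[[k]] <- sk
    cc$conv_in[[nmB]] <- sk
    a <- nnb_relu(nnb_conv_fwd(L[[nmB]], sk))
    cc$relu_out[[nmB]] <- a
  }
  cc$conv_in[["mid"]] <- a
  a <- nnb_relu(nnb_conv_fwd(L[["mid"]], a))
  cc$relu_out[["mid"]] <- a
  for (k in seq(d, 1L)) {
    nmU <- paste0("decU", k); nmM <- paste0("decM", k)
    sz <- dim(skips[[k]])[1:2]
    cc$pre_up_dim[[nmU]] <- dim(a)[1:2]
    up <- cpp_upsampleb(a, sz[1], sz[2])
    cc$conv_in[[nmU]] <- up
    u <- nnb_relu(nnb_conv_fwd(L[[nmU]], up))
    cc$relu_out[[nmU]] <- u
    cat_ <- nnb_concat(skips[[k]], u)
    cc$conv_in[[nmM]] <- cat_
    a <- nnb_relu(nnb_conv_fwd(L[[nmM]], cat_))
    cc$relu_out[[nmM]] <- a
  }
  cc$conv_in[["out"]] <- a
  z <- nnb_conv_fwd(L[["out"]], a)
  prob <- nn_sigmoid(z)
  res <- list(prob = prob)
  if (keep_cache) res$cache <- cc
  res
}

# Backward from d(loss)/d(pre-sigmoid logits) `gz` (H, W, 1, B).
unet_backward <- function(model, cache, gz) {
  d <- model$depth
  L <- model$layers
  w <- model$widths
  grads <- list()
  bw <- nnb_conv_bwd(L[["out"]], cache$conv_in[["out"]], gz)
  grads[["out"]] <- list(gw = bw$gw, gb = bw$gb)
  g <- bw$gx
  gskips <- vector("list", d)
  for (k in seq_len(d)) {          # reverse of decoder order d..1
    nmU <- paste0("decU", k); nmM <- paste0("decM", k)
    g <- g * (cache$relu_out[[nmM]] > 0)
    bw <- nnb_conv_bwd(L[[nmM]], cache$conv_in[[nmM]], g)
    grads[[nmM]] <- list(gw = bw$gw, gb = bw$gb)
    gcat <- bw$gx
    gskips[[k]] <- gcat[, , seq_len(w[k]), , drop = FALSE]
    gu <- gcat[, , w[k] + seq_len(w[k]), , drop = FALSE]
    gu <- gu * (cache$relu_out[[nmU]] > 0)
    bw <- nnb_conv_bwd(L[[nmU]], cache$conv_in[[nmU]], gu)
    grads[[nmU]] <- list(gw = bw$gw, gb = bw$gb)
    pud <- cache$pre_up_dim[[nmU]]
    g <- cpp_upsampleb_backward(bw$gx, pud[1], pud[2])
  }
  g <- g * (cache$relu_out[["mid"]] > 0)
  bw <- nnb_conv_bwd(L[["mid"]], cache$conv_in[["mid"]], g)
  grads[["mid"]] <- list(gw = bw$gw, gb = bw$gb)
  g <- bw$gx
  for (k in seq(d, 1L)) {
    nmA <- paste0("encA", k); nmB <- paste0("encB", k)
    g <- g * (cache$relu_out[[nmB]] > 0)
    bw <- nnb_conv_bwd(L[[nmB]], cache$conv_in[[nmB]], g)
    grads[[nmB]] <- list(gw = bw$gw, gb = bw$gb)
    g <- bw$gx + gskips[[k]]
    g <- g * (cache$relu_out[[nmA]] > 0)
    bw <- nnb_conv_bwd(L[[nmA]], cache$conv_in[[nmA]], g, want_gx = k > 1L)
    grads[[nmA]] <- list(gw = bw$gw, gb = bw$gb)
    g <- bw$gx
  }
  grads[names(model$layers)]
}
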