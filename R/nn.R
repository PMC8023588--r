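# Internal CNN engine shared by the autoencoder (frame selection) and the
# U-net segmenter: 3x3 convolutions (stride 1 or 2, zero "same" padding),
# ReLU, nearest-neighbour x2 upsampling with crop-to-size, sigmoid head,
# and an Adam optimiser. Weights live in plain R lists so models are
# serialisable with saveRDS and fully deterministic given the seed.

nn_conv_init <- function(cin, cout, kh = 3L, kw = 3L, stride = 1L) {
  k <- kh * kw * cin
  list(
    w = matrix(rnorm(k * cout, 0, sqrt(2 / k)), nrow = k, ncol = cout),
    b = numeric(cout),
    kh = kh, kw = kw, cin = cin, cout = cout, stride = as.integer(stride)
  )
}

nn_sigmoid <- function(z) 1 / (1 + exp(-z))

# ---- Adam ------------------------------------------------------------------

nn_adam_init <- function(params) {
  st <- lapply(params, function(p) list(
    mw = p$w * 0, vw = p$w * 0, mb = p$b * 0, vb = p$b * 0
  ))
  list(t = 0L, layers = st, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

nn_adam_step <- function(params, grads, state, lr) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  for (i in seq_along(params)) {
    s <- state$layers[[i]]
    s$mw <- b1 * s$mw + (1 - b1) * grads[[i]]$gw
    s$vw <- b2 * s$vw + (1 - b2) * grads[[i]]$gw^2
    s$mb <- b1 * s$mb + (1 - b1) * grads[[i]]$gb
    s$vb <- b2 * s$vb + (1 - b2) * grads[[i]]$gb^2
    params[[i]]$w <- params[[i]]$w - lr * (s$mw / c1) / (sqrt(s$vw / c2) + state$eps)
    params[[i]]$b <- params[[i]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + state$eps)
    state$layers[[i]] <- s
  }
  list(params = params, state = state)
}

nn_zero_grads <- function(params) {
  lapply(params, function(p) list(gw = p$w * 0, gb = p$b * 0))
}

nn_acc_grads <- function(acc, g) {
  for (i in seq_along(acc)) {
    acc[[i]]$gw <- acc[[i]]$gw + g[[i]]$gw
    acc[[i]]$gb <- acc[[i]]$gb + g[[i]]$gb
  }
  acc
}

nn_scale_grads <- function(acc, s) {
  lapply(acc, function(g) list(gw = g$gw * s, gb = g$gb * s))
}
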