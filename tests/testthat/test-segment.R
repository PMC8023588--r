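test_that("class weights are inverse-prevalence and sum to one", {
  expect_equal(class_weights_from_prevalence(0.5),
               c(calcific = 0.5, other = 0.5))
  expect_equal(class_weights_from_prevalence(0.1),
               c(calcific = 0.9, other = 0.1))
  for (p in c(0.01, 0.2, 0.37, 0.8))
    expect_equal(sum(class_weights_from_prevalence(p)), 1)
  expect_error(class_weights_from_prevalence(0), "strictly inside")
  expect_error(class_weights_from_prevalence(1), "strictly inside")
})

test_that("weighted BCE matches hand computations and limits", {
  # single pixel, y = 1, p = 0.5, w_c = 0.9
  expect_equal(weighted_bce(0.5, 1, c(0.9, 0.1)), 0.9 * log(2))
  # perfect prediction: loss tends to zero
  y <- matrix(c(1, 0, 1, 0), 2)
  p_perfect <- matrix(c(1, 0, 1, 0), 2)
  expect_lt(weighted_bce(p_perfect, y, c(0.9, 0.1)), 1e-5)
  # equal weights halve the standard BCE
  set.seed(1)
  p <- matrix(runif(20, 0.05, 0.95), 4)
  yy <- matrix(rbinom(20, 1, 0.5), 4)
  std <- -mean(yy * log(p) + (1 - yy) * log(1 - p))
  expect_equal(weighted_bce(p, yy, c(0.5, 0.5)), std / 2)
  expect_error(weighted_bce(p, yy[1:2, ], c(0.5, 0.5)), "do not match")
})

test_that("weighted BCE gradient matches finite differences", {
  set.seed(2)
  w <- c(0.8, 0.2)
  p <- matrix(runif(12, 0.1, 0.9), 3)
  y <- matrix(rbinom(12, 1, 0.4), 3)
  g_analytic <- (-w[1] * y / p + w[2] * (1 - y) / (1 - p)) / length(p)
  eps <- 1e-6
  for (idx in sample(12, 5)) {
    pp <- p; pp[idx] <- pp[idx] + eps
    pm <- p; pm[idx] <- pm[idx] - eps
    g_num <- (weighted_bce(pp, y, w) - weighted_bce(pm, y, w)) / (2 * eps)
    expect_lt(abs(g_num - g_analytic[idx]), 1e-4)
  }
})

test_that("the segmenter produces sigmoid probability maps of input shape", {
  set.seed(3)
  model <- build_segmenter(widths = c(2L, 4L), seed = 7L)
  frames <- lapply(1:3, function(i) matrix(runif(40 * 24), 40, 24))
  probs <- predict_probability(model, frames)
  expect_length(probs, 3L)
  for (p in probs) {
    expect_equal(dim(p), c(40L, 24L))
    expect_true(all(p > 0 & p < 1))
  }
  masks <- threshold_masks(probs, 0.5)
  expect_true(all(vapply(masks, function(m) all(m %in% 0:1), logical(1))))
  expect_identical(masks[[1]] == 1L, probs[[1]] >= 0.5)
  # rebuilding with the same seed reproduces the weights
  model2 <- build_segmenter(widths = c(2L, 4L), seed = 7L)
  expect_identical(model$layers, model2$layers)
})

make_seg_frames <- function(n, seed, h = 32L, w = 48L) {
  # simple synthetic task: a dark band is the positive class
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    img <- matrix(runif(h * w, 0.5, 1), h, w)
    r0 <- sample(5:(h - 12), 1)
    cols <- sample(seq_len(w - 16), 1) + 0:15
    img[r0:(r0 + 6), cols] <- img[r0:(r0 + 6), cols] * 0.2
    mask <- matrix(0L, h, w)
    mask[r0:(r0 + 6), cols] <- 1L
    structure(list(image = img, mask = mask,
                   provenance = list(shifts = integer(w),
                                     guidewire = integer(0))),
              class = "aligned_frame")
  })
}

test_that("early stopping fires per contract and training is reproducible", {
  tr <- make_seg_frames(8, 10)
  va <- make_seg_frames(4, 20)
  cfg <- seg_train_config(widths = c(2L, 4L), max_epochs = 8L,
                          batch_size = 4L, max_restarts = 0L, seed = 5L)
  fit <- train_segmenter(tr, va, cfg)
  expect_lte(fit$record$stopped_epoch, cfg$max_epochs)
  expect_lte(fit$record$best_epoch, fit$record$stopped_epoch)
  # reproducibility: identical records and predictions
  fit2 <- train_segmenter(tr, va, cfg)
  expect_identical(fit$record$train_loss, fit2$record$train_loss)
  expect_identical(fit$record$val_loss, fit2$record$val_loss)
  expect_identical(fit$model$layers, fit2$model$layers)
  # training loss decreases over the first epochs (trend)
  tl <- fit$record$train_loss
  expect_lt(mean(tail(tl, 3)), mean(head(tl, 2)))
  expect_error(train_segmenter(list(), va, cfg), "non-empty")
})

test_that("the patience rule stops exactly after patience flat epochs", {
  # constant validation loss from epoch 1 stops at 1 + patience; a strictly
  # improving one runs to max_epochs. Emulated by direct rule replay on the
  # recorded losses of a real run.
  tr <- make_seg_frames(6, 30)
  va <- tr[1:2]    # validation identical to training head: loss tracks train
  cfg <- seg_train_config(widths = c(2L, 2L), max_epochs = 20L,
                          patience = 3L, batch_size = 6L,
                          max_restarts = 0L, seed = 8L)
  fit <- train_segmenter(tr, va, cfg)
  vl <- fit$record$val_loss
  n <- length(vl)
  if (fit$record$stopped_epoch < cfg$max_epochs) {
    # the last `patience` epochs failed to improve on the best before them
    best_before <- min(vl[seq_len(n - cfg$patience)])
    expect_true(all(vl[(n - cfg$patience + 1L):n] >= best_before))
  }
  expect_identical(which.min(vl), fit$record$best_epoch)
})

test_that("a compact U-net learns an easy high-contrast task", {
  tr <- make_seg_frames(40, 100)
  va <- make_seg_frames(8, 200)
  te <- make_seg_frames(10, 300)
  cfg <- seg_train_config(widths = c(4L, 8L), max_epochs = 40L,
                          batch_size = 4L, seed = 1L)
  fit <- train_segmenter(tr, va, cfg)
  probs <- predict_probability(fit$model, te)
  f1 <- f1_per_class(threshold_masks(probs), lapply(te, `[[`, "mask"))
  expect_gte(f1["calcific"], 0.8)
})
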