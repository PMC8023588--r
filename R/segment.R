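#' Segmentation training configuration
#'
#' Training contract for the compact U-net pixel classifier: Adam, weighted
#' binary cross-entropy, early stopping on the validation loss with a
#' patience of 5 epochs.
#'
#' @param lr Adam learning rate.
#' @param batch_size Frames per batch.
#' @param max_epochs Upper bound on training epochs.
#' @param patience Consecutive epochs without validation improvement before
#'   stopping.
#' @param class_weights `"auto"` (inverse class prevalence of the training
#'   set, summing to one) or a numeric `c(w_calcific, w_other)`.
#' @param widths Channel widths of the U-net stages.
#' @param max_restarts With a small net and few frames, a run occasionally
#'   stalls in a poor basin; if after at least 10 epochs the final training
#'   loss has not dropped below a quarter of the first epoch's, training is
#'   restarted (deterministically) from a re-derived seed, at most this many
#'   times.
#' @param seed Integer seed controlling initialisation and shuffling.
#' @return A `seg_train_config` list.
#' @export
seg_train_config <- function(lr = 1e-3, batch_size = 8L, max_epochs = 50L,
                             patience = 5L, class_weights = "auto",
                             widths = c(8L, 16L, 32L), max_restarts = 2L,
                             seed = 1L) {
  stopifnot(lr > 0, batch_size >= 1, max_epochs >= 1, patience >= 1)
  if (is.numeric(class_weights)) {
    stopifnot(length(class_weights) == 2, all(class_weights > 0),
              abs(sum(class_weights) - 1) < 1e-8)
  } else stopifnot(identical(class_weights, "auto"))
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 class_weights = class_weights,
                 widths = as.integer(widths),
                 max_restarts = as.integer(max_restarts),
                 seed = as.integer(seed)),
            class = "seg_train_config")
}

#' Loss weights from class prevalence
#'
#' Weights inversely proportional to class prevalence, normalised to sum to
#' one: `w_calcific = (1/p) / (1/p + 1/(1-p)) = 1 - p`. At the typical 10%
#' calcific prevalence this weights calcific pixels 0.9 and other pixels
#' 0.1.
#'
#' @param p_calcific Fraction of calcific pixels in the training set,
#'   strictly inside `(0, 1)`.
#' @return Named numeric `c(calcific =, other =)`, summing to one.
#' @export
class_weights_from_prevalence <- function(p_calcific) {
  if (!is.finite(p_calcific) || p_calcific <= 0 || p_calcific >= 1)
    stop("class prevalence must lie strictly inside (0, 1); got ",
         p_calcific, " (degenerate training set)")
  c(calcific = 1 - p_calcific, other = p_calcific)
}

#' Weighted binary cross-entropy
#'
#' Mean over pixels of `-(w_c * y * log(p) + w_o * (1 - y) * log(1 - p))`,
#' with probabilities clipped away from 0 and 1.
#'
#' @param prob_map Predicted probabilities (any numeric array).
#' @param target_mask Binary targets, same shape.
#' @param weights `c(w_calcific, w_other)`.
#' @param eps Clipping epsilon.
#' @return Scalar loss.
#' @export
weighted_bce <- function(prob_map, target_mask, weights, eps = 1e-7) {
  if (length(prob_map) != length(target_mask))
    stop("probability map and mask shapes do not match")
  p <- pmin(pmax(prob_map, eps), 1 - eps)
  y <- target_mask
  -mean(weights[1] * y * log(p) + weights[2] * (1 - y) * log(1 - p))
}

#' Build a compact U-net segmenter
#'
#' Encoder--decoder with skip connections and a single-channel sigmoid head
#' producing per-pixel calcific probabilities at input resolution.
#'
#' @param widths Channel widths per stage.
#' @param seed Optional seed for weight initialisation (otherwise the
#'   current RNG stream is used).
#' @return An `oct_unet` model.
#' @export
build_segmenter <- function(widths = c(8L, 16L, 32L), seed = NULL) {
  if (is.null(seed)) unet_build(widths)
  else with_seed(seed, unet_build(widths))
}

seg_xy <- function(frames) {
  stopifnot(length(frames) >= 1)
  list(x = lapply(frames, function(f) f$image),
       y = lapply(frames, function(f) f$mask))
}

seg_epoch_loss <- function(model, xs, ys, w, batch) {
  tot <- 0
  for (chunk in split(seq_along(xs), ceiling(seq_along(xs) / batch))) {
    pb <- unet_forward(model, nn_batchify(xs[chunk]))$prob
    tot <- tot + weighted_bce(pb, nn_batchify(ys[chunk]), w) * length(chunk)
  }
  tot / length(xs)
}

#' Train the U-net segmenter with early stopping
#'
#' Adam at `cfg$lr`, weighted binary cross-entropy with dataset-level class
#' weights, stopping when the validation loss has not improved for
#' `cfg$patience` consecutive epochs (or at `cfg$max_epochs`). The returned
#' model carries the weights of the best validation epoch. Fully
#' deterministic given `cfg$seed`.
#'
#' @param train_frames,val_frames Non-empty lists of `aligned_frame`
#'   objects (image + mask).
#' @param cfg A [seg_train_config()].
#' @return List with `model` and `record` (per-epoch train/val loss,
#'   `stopped_epoch`, `best_epoch`, class weights used).
#' @export
train_segmenter <- function(train_frames, val_frames, cfg = seg_train_config()) {
  seg_with_restarts(cfg, function(seed1) {
    cfg1 <- cfg; cfg1$seed <- seed1
    train_segmenter_once(train_frames, val_frames, cfg1)
  })
}

# Retry policy shared by both trainers: restart (with a re-derived seed) when
# the final training loss shows the run stalled far above a converged level.
seg_with_restarts <- function(cfg, run) {
  restarts <- cfg$max_restarts %||% 0L
  attempt <- 0L
  repeat {
    seed_a <- as.integer((cfg$seed + 100003 * attempt) %% .Machine$integer.max)
    fit <- run(seed_a)
    tl <- fit$record$train_loss
    fit$record$attempts <- attempt + 1L
    if (length(tl) < 10L || tail(tl, 1L) <= 0.25 * tl[1L] ||
        attempt >= restarts)
      return(fit)
    attempt <- attempt + 1L
  }
}

train_segmenter_once <- function(train_frames, val_frames, cfg) {
  if (length(train_frames) == 0 || length(val_frames) == 0)
    stop("training and validation sets must be non-empty")
  tr <- seg_xy(train_frames)
  va <- seg_xy(val_frames)
  w <- seg_resolve_weights(cfg, tr$y)
  with_seed(cfg$seed, {
    model <- unet_build(cfg$widths)
    n <- length(tr$x)
    perms <- t(vapply(seq_len(cfg$max_epochs), function(i) sample.int(n),
                      integer(n)))
    fit <- cpp_unet_train(nn_batchify(tr$x), nn_batchify(tr$y),
                          nn_batchify(va$x), nn_batchify(va$y),
                          model$layers, model$widths, perms,
                          cfg$batch_size, cfg$lr, w[1], w[2], cfg$patience)
    for (i in seq_along(model$layers)) {
      model$layers[[i]]$w <- fit$layers[[i]]$w
      model$layers[[i]]$b <- as.numeric(fit$layers[[i]]$b)
    }
    list(model = model,
         record = list(train_loss = fit$train_loss, val_loss = fit$val_loss,
                       stopped_epoch = fit$stopped_epoch,
                       best_epoch = fit$best_epoch, class_weights = w))
  })
}

seg_resolve_weights <- function(cfg, masks) {
  if (identical(cfg$class_weights, "auto")) {
    p <- mean(unlist(lapply(masks, mean)))
    class_weights_from_prevalence(p)
  } else cfg$class_weights
}

# Double-precision reference trainer (fixed epochs, no validation); the
# oracle the single-precision training engine is checked against in tests.
seg_train_reference_fixed <- function(train_frames, cfg, epochs) {
  tr <- seg_xy(train_frames)
  w <- seg_resolve_weights(cfg, tr$y)
  npix <- length(tr$x[[1L]])
  with_seed(cfg$seed, {
    model <- unet_build(cfg$widths)
    opt <- nn_adam_init(model$layers)
    n <- length(tr$x)
    train_loss <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      ep_loss <- 0
      for (chunk in split(perm, ceiling(seq_along(perm) / cfg$batch_size))) {
        xb <- nn_batchify(tr$x[chunk])
        yb <- nn_batchify(tr$y[chunk])
        f <- unet_forward(model, xb, keep_cache = TRUE)
        loss <- weighted_bce(f$prob, yb, w)
        ep_loss <- ep_loss + loss * length(chunk)
        gz <- (-w[1] * yb * (1 - f$prob) + w[2] * (1 - yb) * f$prob) /
          (npix * length(chunk))
        grads <- unet_backward(model, f$cache, gz)
        step <- nn_adam_step(model$layers, grads, opt, cfg$lr)
        model$layers <- step$params
        opt <- step$state
      }
      train_loss[ep] <- ep_loss / n
    }
    list(model = model, record = list(train_loss = train_loss,
                                      class_weights = w))
  })
}

#' Train for a fixed number of epochs (no validation)
#'
#' Used to fit the final model on the full training set for the average
#' number of epochs observed during cross-validation.
#'
#' @param train_frames List of `aligned_frame` objects.
#' @param cfg A [seg_train_config()].
#' @param epochs Number of epochs to run.
#' @return List with `model` and `record` (per-epoch train loss).
#' @export
train_segmenter_fixed <- function(train_frames, cfg, epochs) {
  seg_with_restarts(cfg, function(seed1) {
    cfg1 <- cfg; cfg1$seed <- seed1
    train_segmenter_fixed_once(train_frames, cfg1, epochs)
  })
}

train_segmenter_fixed_once <- function(train_frames, cfg, epochs) {
  stopifnot(length(train_frames) >= 1, epochs >= 1)
  tr <- seg_xy(train_frames)
  w <- seg_resolve_weights(cfg, tr$y)
  with_seed(cfg$seed, {
    model <- unet_build(cfg$widths)
    n <- length(tr$x)
    perms <- t(vapply(seq_len(epochs), function(i) sample.int(n),
                      integer(n)))
    fit <- cpp_unet_train(nn_batchify(tr$x), nn_batchify(tr$y),
                          numeric(0), numeric(0),
                          model$layers, model$widths, perms,
                          cfg$batch_size, cfg$lr, w[1], w[2], 0L)
    for (i in seq_along(model$layers)) {
      model$layers[[i]]$w <- fit$layers[[i]]$w
      model$layers[[i]]$b <- as.numeric(fit$layers[[i]]$b)
    }
    list(model = model,
         record = list(train_loss = fit$train_loss, class_weights = w))
  })
}

#' Predict per-pixel calcific probabilities
#'
#' @param model A trained `oct_unet`.
#' @param frames List of `aligned_frame` objects or image matrices.
#' @param batch Forward-pass batch size.
#' @return List of probability matrices in `[0, 1]`, one per frame.
#' @export
predict_probability <- function(model, frames, batch = 8L) {
  imgs <- as_image_list(frames)
  out <- vector("list", length(imgs))
  for (chunk in split(seq_along(imgs), ceiling(seq_along(imgs) / batch))) {
    pb <- unet_forward(model, nn_batchify(imgs[chunk]))$prob
    for (i in seq_along(chunk)) out[[chunk[i]]] <- pb[, , 1L, i]
  }
  out
}

#' Threshold probability maps into binary masks
#'
#' Pixels with probability at or above the threshold are labelled calcific.
#'
#' @param prob_maps List of probability matrices.
#' @param threshold Decision threshold (default 0.5).
#' @return List of binary (0/1 integer) matrices.
#' @export
threshold_masks <- function(prob_maps, threshold = 0.5) {
  lapply(prob_maps, function(p) {
    m <- matrix(0L, nrow(p), ncol(p))
    m[p >= threshold] <- 1L
    m
  })
}
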