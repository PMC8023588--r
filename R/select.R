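#' Sampler configuration
#'
#' Settings for the two training-frame subset selectors: equal z-spacing and
#' deep-feature clustering (per-VOI autoencoder, bottleneck features, PCA,
#' k-medoids).
#'
#' @param method `"equal_spacing"`, `"clustering"` or `"all"`.
#' @param ratio Sampling ratio in `(0, 1]`: the fraction of frames to select
#'   per volume of interest (typical values 1/2, 1/3, 1/10).
#' @param ae_epochs,ae_lr,ae_batch Autoencoder training schedule: epochs,
#'   Adam learning rate, batch size.
#' @param ae_widths Channel widths of the autoencoder stages (the last entry
#'   is the bottleneck width).
#' @param pca_variance Minimum cumulative explained-variance ratio retained
#'   by the PCA reduction.
#' @param feature_pool `"gap"` pools each bottleneck channel to its spatial
#'   mean (dimension independent of frame size); `"flatten"` keeps every
#'   bottleneck unit.
#' @param seed Integer seed controlling all sampler randomness.
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(method = c("clustering", "equal_spacing", "all"),
                           ratio = 1 / 10,
                           ae_epochs = 100L, ae_lr = 0.001, ae_batch = 64L,
                           ae_widths = c(4L, 8L, 16L, 32L),
                           pca_variance = 0.95,
                           feature_pool = c("gap", "flatten"),
                           seed = 1L) {
  method <- match.arg(method)
  feature_pool <- match.arg(feature_pool)
  stopifnot(ratio > 0, ratio <= 1, pca_variance > 0, pca_variance <= 1,
            ae_epochs >= 1, ae_lr > 0, ae_batch >= 1)
  structure(list(method = method, ratio = ratio,
                 ae_epochs = as.integer(ae_epochs), ae_lr = ae_lr,
                 ae_batch = as.integer(ae_batch),
                 ae_widths = as.integer(ae_widths),
                 pca_variance = pca_variance, feature_pool = feature_pool,
                 seed = as.integer(seed)),
            class = "sampler_config")
}

#' Number of frames to select from a volume of interest
#'
#' `ceiling(n_frames * ratio)`, never below 1: one-third of a 9-frame volume
#' is 3 frames, one-tenth of 10 frames is 1 frame.
#'
#' @param n_frames Frames in the volume.
#' @param ratio Sampling ratio in `(0, 1]`.
#' @return Integer target count.
#' @export
target_count <- function(n_frames, ratio) {
  stopifnot(n_frames >= 1, ratio > 0, ratio <= 1)
  max(1L, as.integer(ceiling(n_frames * ratio)))
}

#' Equal z-spacing frame selection
#'
#' Selects frames at a fixed stride along the pullback axis, starting at the
#' first frame: stride `round(1/ratio)`, i.e. every third frame for ratio
#' one-third. The selection is deterministic. If the stride rule over- or
#' under-shoots [target_count()] (possible only for ratios that are not
#' reciprocals of integers) the set is trimmed from the end or padded with
#' the evenly-spread remaining frames so that the cardinality contract holds
#' for every ratio.
#'
#' @param n_frames Frames in the volume.
#' @param ratio Sampling ratio in `(0, 1]`.
#' @param voi_id Optional identifier recorded in the plan.
#' @return A `sampling_plan` with 0-based `selected` frame indices.
#' @export
equal_spacing_indices <- function(n_frames, ratio, voi_id = NA) {
  m <- target_count(n_frames, ratio)
  s <- max(1L, as.integer(round(1 / ratio)))
  idx <- seq.int(0L, n_frames - 1L, by = s)
  if (length(idx) > m) idx <- idx[seq_len(m)]
  if (length(idx) < m) {
    pool <- setdiff(seq_len(n_frames) - 1L, idx)
    extra <- pool[unique(round(seq(1, length(pool),
                                   length.out = m - length(idx))))]
    idx <- sort(c(idx, extra))
  }
  new_sampling_plan(voi_id, "equal_spacing", ratio, idx, seed = NA_integer_)
}

new_sampling_plan <- function(voi_id, method, ratio, selected, seed,
                              details = list()) {
  structure(list(voi_id = voi_id, method = method, ratio = ratio,
                 selected = as.integer(selected), seed = seed,
                 details = details),
            class = "sampling_plan")
}

#' @export
print.sampling_plan <- function(x, ...) {
  cat(sprintf("<sampling_plan> voi: %s, method: %s, ratio: %.3g, %d frames\n",
              as.character(x$voi_id), x$method, x$ratio, length(x$selected)))
  cat(" selected (0-based):", x$selected, "\n")
  invisible(x)
}

as_image_list <- function(frames) {
  lapply(frames, function(f) if (inherits(f, "aligned_frame")) f$image else f)
}

#' Train a per-VOI convolutional autoencoder
#'
#' Trains the compact encoder--bottleneck--decoder network to reconstruct
#' the volume's preprocessed frames under mean-squared-error loss, for
#' exactly `ae_epochs` epochs with Adam at `ae_lr` and batch size
#' `ae_batch`. All randomness (weight initialisation, batch shuffling) is
#' governed by `cfg$seed`; the caller's RNG state is untouched.
#'
#' @param frames List of `aligned_frame` objects or plain image matrices
#'   (all the same shape, intensities in `[0, 1]`).
#' @param cfg A [sampler_config()].
#' @return List with `model` (an `oct_autoencoder`) and `record` (per-epoch
#'   mean training loss, final mean per-pixel squared error).
#' @export
train_autoencoder <- function(frames, cfg = sampler_config()) {
  imgs <- as_image_list(frames)
  stopifnot(length(imgs) >= 1)
  with_seed(cfg$seed, {
    model <- ae_build(cfg$ae_widths)
    n <- length(imgs)
    perms <- t(vapply(seq_len(cfg$ae_epochs), function(i) sample.int(n),
                      integer(n)))
    fit <- cpp_ae_train(nn_batchify(imgs), model$layers,
                        model$widths, perms, cfg$ae_batch, cfg$ae_lr)
    for (i in seq_along(model$layers)) {
      model$layers[[i]]$w <- fit$layers[[i]]$w
      model$layers[[i]]$b <- as.numeric(fit$layers[[i]]$b)
    }
    final_mse <- autoencoder_mse(model, imgs, batch = cfg$ae_batch)
    list(model = model,
         record = list(epoch_loss = fit$epoch_loss, final_mse = final_mse))
  })
}

# Double-precision reference trainer (same contract as train_autoencoder);
# kept as the oracle that the single-precision training engine is checked
# against in the tests.
ae_train_reference <- function(frames, cfg) {
  imgs <- as_image_list(frames)
  with_seed(cfg$seed, {
    model <- ae_build(cfg$ae_widths)
    opt <- nn_adam_init(model$layers)
    n <- length(imgs)
    npix <- length(imgs[[1L]])
    losses <- numeric(cfg$ae_epochs)
    for (ep in seq_len(cfg$ae_epochs)) {
      perm <- sample.int(n)
      ep_loss <- 0
      for (chunk in split(perm, ceiling(seq_along(perm) / cfg$ae_batch))) {
        xb <- nn_batchify(imgs[chunk])
        f <- ae_forward(model, xb, keep_cache = TRUE)
        diff <- f$recon - xb
        loss <- mean(diff^2)
        if (!is.finite(loss))
          stop("non-finite autoencoder loss at epoch ", ep)
        ep_loss <- ep_loss + loss * length(chunk)
        gz <- (2 * diff / (npix * length(chunk))) * f$recon * (1 - f$recon)
        grads <- ae_backward(model, f$cache, gz)
        step <- nn_adam_step(model$layers, grads, opt, cfg$ae_lr)
        model$layers <- step$params
        opt <- step$state
      }
      losses[ep] <- ep_loss / n
    }
    final_mse <- autoencoder_mse(model, imgs, batch = cfg$ae_batch)
    list(model = model,
         record = list(epoch_loss = losses, final_mse = final_mse))
  })
}

#' Mean per-pixel squared reconstruction error over a set of frames
#'
#' @param model A trained `oct_autoencoder`.
#' @param frames Frames as in [train_autoencoder()].
#' @param batch Forward-pass batch size.
#' @return Mean squared error between inputs and reconstructions.
#' @export
autoencoder_mse <- function(model, frames, batch = 16L) {
  imgs <- as_image_list(frames)
  tot <- 0
  for (chunk in split(seq_along(imgs), ceiling(seq_along(imgs) / batch))) {
    xb <- nn_batchify(imgs[chunk])
    tot <- tot + sum((ae_forward(model, xb)$recon - xb)^2)
  }
  tot / (length(imgs) * length(imgs[[1L]]))
}

#' Extract per-frame bottleneck feature vectors
#'
#' Runs a forward pass through the trained autoencoder and reduces the
#' bottleneck feature maps to one vector per frame: spatial global-average
#' pooling per channel (default) or full flattening.
#'
#' @param model A trained `oct_autoencoder`.
#' @param frames Frames shaped as at training time.
#' @param pool `"gap"` or `"flatten"`.
#' @param batch Forward-pass batch size.
#' @return A `feature_matrix`: `matrix` (rows = frames), `frame_ids`
#'   (0-based), `stage = "bottleneck"`.
#' @export
extract_bottleneck_features <- function(model, frames,
                                        pool = c("gap", "flatten"),
                                        batch = 16L) {
  pool <- match.arg(pool)
  imgs <- as_image_list(frames)
  rows <- vector("list", length(imgs))
  for (chunk in split(seq_along(imgs), ceiling(seq_along(imgs) / batch))) {
    xb <- nn_batchify(imgs[chunk])
    bn <- ae_forward(model, xb)$bottleneck       # (h, w, C, B)
    d <- dim(bn)
    for (i in seq_along(chunk)) {
      sl <- bn[, , , i, drop = FALSE]
      rows[[chunk[i]]] <- if (pool == "gap")
        apply(array(sl, d[1:3]), 3, mean)
      else as.numeric(sl)
    }
  }
  new_feature_matrix(do.call(rbind, rows), seq_along(imgs) - 1L, "bottleneck")
}

new_feature_matrix <- function(m, frame_ids, stage) {
  structure(list(matrix = m, frame_ids = as.integer(frame_ids),
                 stage = stage),
            class = "feature_matrix")
}

#' Reduce feature dimensionality by PCA
#'
#' Centres the features and keeps the smallest number of leading principal
#' components whose cumulative explained-variance ratio reaches `variance`.
#' If the features have no variance at all (identical frames) a single
#' constant component is returned with a warning.
#'
#' @param features A `feature_matrix` (stage `"bottleneck"`) or plain matrix.
#' @param variance Minimum cumulative explained-variance ratio in `(0, 1]`.
#' @return A `feature_matrix` with `stage = "pca"`; attribute
#'   `explained_ratio` holds the per-component ratios of the retained
#'   components.
#' @export
reduce_pca <- function(features, variance = 0.95) {
  stopifnot(variance > 0, variance <= 1)
  m <- if (inherits(features, "feature_matrix")) features$matrix else features
  ids <- if (inherits(features, "feature_matrix")) features$frame_ids
         else seq_len(nrow(m)) - 1L
  stopifnot(nrow(m) >= 2)
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  if (sum(ev) <= 0) {
    warning("features have zero variance; returning one constant component")
    out <- new_feature_matrix(matrix(0, nrow(m), 1L), ids, "pca")
    attr(out, "explained_ratio") <- 1
    return(out)
  }
  ratio <- ev / sum(ev)
  keep <- which(cumsum(ratio) >= variance - 1e-12)[1L]
  keep <- min(keep, nrow(m) - 1L, ncol(pc$x))
  out <- new_feature_matrix(pc$x[, seq_len(keep), drop = FALSE], ids, "pca")
  attr(out, "explained_ratio") <- ratio[seq_len(keep)]
  out
}

col_mins <- function(D, rows) {
  if (length(rows) == 1L) return(D[rows, ])
  do.call(pmin, lapply(rows, function(i) D[i, ]))
}

#' k-medoids clustering by PAM
#'
#' Partitioning around medoids on the pairwise Euclidean distance matrix:
#' greedy build phase (first medoid minimises total distance; each further
#' medoid maximises the cost reduction) followed by swap phase (repeatedly
#' apply the best strictly improving medoid/non-medoid swap until none
#' exists). All ties break toward the lowest frame index, making the result
#' deterministic; the `seed` argument is accepted for interface parity and
#' recorded but not consumed.
#'
#' @param points A `feature_matrix` or numeric matrix (rows = frames).
#' @param k Number of clusters, `1 <= k <= n`.
#' @param seed Recorded in the result; PAM itself is deterministic.
#' @return A `cluster_result`: `k`, `assignments` (per frame, index into
#'   `medoid_frame_ids`), `medoid_frame_ids` (0-based, ascending),
#'   `total_cost` (sum of distances to assigned medoids), `build_cost`.
#' @export
k_medoids <- function(points, k, seed = NA_integer_) {
  m <- if (inherits(points, "feature_matrix")) points$matrix else points
  ids <- if (inherits(points, "feature_matrix")) points$frame_ids
         else seq_len(nrow(m)) - 1L
  n <- nrow(m)
  if (k < 1 || k > n) stop("k must be in [1, n]; got k = ", k, ", n = ", n)
  D <- as.matrix(dist(m))

  # build phase
  med <- which.min(colSums(D))
  dn <- D[med, ]
  while (length(med) < k) {
    cand <- setdiff(seq_len(n), med)
    gains <- vapply(cand, function(h) sum(pmax(dn - D[h, ], 0)), numeric(1))
    h <- cand[which.max(gains)]          # which.max breaks ties at lowest
    med <- c(med, h)
    dn <- pmin(dn, D[h, ])
  }
  build_cost <- sum(dn)

  # swap phase: med kept sorted, scan order (medoid asc, candidate asc), so
  # the first strictly best swap found also realises the lowest-index
  # tie-break
  med <- sort(med)
  repeat {
    best <- list(delta = -1e-12, m = NA, h = NA)
    others <- setdiff(seq_len(n), med)
    dmat <- D[med, , drop = FALSE]
    dn <- col_mins(D, med)
    cost <- sum(dn)
    ds <- if (length(med) == 1L) rep(Inf, n) else
      apply(dmat, 2, function(col) sort(col, partial = 2)[2])
    for (mi in seq_along(med)) {
      is_near <- dmat[mi, ] <= dn + 1e-15   # points whose nearest is med[mi]
      for (h in others) {
        newd <- ifelse(is_near, pmin(ds, D[h, ]), pmin(dn, D[h, ]))
        delta <- sum(newd) - cost
        if (delta < best$delta) best <- list(delta = delta, m = mi, h = h)
      }
    }
    if (is.na(best$m)) break
    med[best$m] <- best$h
    med <- sort(med)
  }

  med <- sort(med)
  dmat <- D[med, , drop = FALSE]
  assign_idx <- apply(dmat, 2, which.min)    # lowest medoid index on ties
  total_cost <- sum(dmat[cbind(assign_idx, seq_len(n))])
  structure(list(k = as.integer(k),
                 assignments = as.integer(assign_idx),
                 medoid_frame_ids = ids[med],
                 total_cost = total_cost,
                 build_cost = build_cost,
                 seed = seed),
            class = "cluster_result")
}

#' Deep-feature clustering frame selection
#'
#' The clustering sampler: train the per-VOI autoencoder, collect bottleneck
#' features, reduce them by PCA, run k-medoids with k equal to the number of
#' frames to select, and return the medoid frames (ascending frame order).
#' When `k >= n_frames` all frames are returned without clustering.
#'
#' @param voi_frames List of preprocessed frames (`aligned_frame` or matrix).
#' @param cfg A [sampler_config()] with `method = "clustering"`.
#' @param voi_id Optional identifier recorded in the plan.
#' @return A `sampling_plan`; `details` records the retained PCA dimension,
#'   final autoencoder reconstruction error and medoid cost.
#' @export
clustering_sample <- function(voi_frames, cfg = sampler_config(),
                              voi_id = NA) {
  n <- length(voi_frames)
  stopifnot(n >= 1)
  m <- target_count(n, cfg$ratio)
  if (m >= n)
    return(new_sampling_plan(voi_id, "clustering", cfg$ratio,
                             seq_len(n) - 1L, cfg$seed))
  tr <- train_autoencoder(voi_frames, cfg)
  feats <- extract_bottleneck_features(tr$model, voi_frames,
                                       pool = cfg$feature_pool)
  red <- reduce_pca(feats, cfg$pca_variance)
  cl <- k_medoids(red, m, seed = cfg$seed)
  new_sampling_plan(voi_id, "clustering", cfg$ratio,
                    sort(cl$medoid_frame_ids), cfg$seed,
                    details = list(pca_dim = ncol(red$matrix),
                                   ae_final_mse = tr$record$final_mse,
                                   medoid_cost = cl$total_cost))
}

#' Select training frames from a volume of interest
#'
#' Dispatches to the selector named in `cfg$method`: all frames, equal
#' z-spacing, or deep-feature clustering.
#'
#' @param voi_frames List of preprocessed frames.
#' @param cfg A [sampler_config()].
#' @param voi_id Optional identifier recorded in the plan.
#' @return A `sampling_plan`.
#' @export
sample_frames <- function(voi_frames, cfg, voi_id = NA) {
  stopifnot(inherits(cfg, "sampler_config"))
  n <- length(voi_frames)
  switch(cfg$method,
    all = new_sampling_plan(voi_id, "all", 1, seq_len(n) - 1L, NA_integer_),
    equal_spacing = equal_spacing_indices(n, cfg$ratio, voi_id),
    clustering = clustering_sample(voi_frames, cfg, voi_id))
}
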