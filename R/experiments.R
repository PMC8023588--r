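# Orchestration of the multi-model comparison protocol: stratified grouped
# cross-validation with a rotating held-out set, the seven-model sampler
# comparison, and the fewer-VOIs experiment. VOIs (never frames) are the unit
# of splitting, so no frame of a held-out volume is ever seen in training.

#' Experiment configuration
#'
#' Desk-scale defaults for the full comparison protocol; every structural
#' element (stratification, held-out rotation, CV folds, early stopping,
#' sampler grid) matches the full-scale protocol and scales up by changing
#' these values.
#'
#' @param n_iterations Held-out rotations (each VOI held out exactly once).
#' @param cv_folds Folds for the inner cross-validation.
#' @param n_shuffles VOI-order shuffles in the fewer-VOIs experiment.
#' @param ratios Sampling ratios of the subset selectors.
#' @param sampler Base [sampler_config()] (seed is overridden per VOI).
#' @param seg Base [seg_train_config()] (seed is overridden per model).
#' @param grid Optional list of `list(lr =, batch_size =)` hyperparameter
#'   candidates; `NULL` uses the single point in `seg`.
#' @param final_epochs Optional fixed epoch count for the final model,
#'   bypassing the inner CV (the full protocol uses the mean CV epoch
#'   count).
#' @param master_seed Seed from which all experiment seeds derive.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(n_iterations = 4L, cv_folds = 5L,
                              n_shuffles = 10L,
                              ratios = c(1 / 2, 1 / 3, 1 / 10),
                              sampler = sampler_config(),
                              seg = seg_train_config(),
                              grid = NULL, final_epochs = NULL,
                              master_seed = 1L) {
  structure(list(n_iterations = as.integer(n_iterations),
                 cv_folds = as.integer(cv_folds),
                 n_shuffles = as.integer(n_shuffles), ratios = ratios,
                 sampler = sampler, seg = seg, grid = grid,
                 final_epochs = final_epochs,
                 master_seed = as.integer(master_seed)),
            class = "experiment_config")
}

#' Stratified held-out rotation and fold assignment
#'
#' Partitions VOIs into `n_iter` disjoint held-out sets covering every VOI
#' exactly once, stratified by label, and assigns each iteration's training
#' VOIs to `k` stratified folds. Deterministic given `seed`.
#'
#' @param labels Character vector of VOI labels (`"normal"` /
#'   `"calcification"`); names (or positions, 0-based) identify VOIs.
#' @param n_iter Number of held-out rotations.
#' @param k Number of CV folds.
#' @param seed Integer seed.
#' @return List of `split_plan` objects: `iteration`, `heldout` (VOI ids),
#'   `folds` (named vector, training VOI id -> fold), `labels`.
#' @export
make_split_plans <- function(labels, n_iter = 4L, k = 5L, seed = 1L) {
  n <- length(labels)
  ids <- names(labels) %||% as.character(seq_len(n) - 1L)
  names(labels) <- ids
  stopifnot(n >= n_iter, n_iter >= 1, k >= 1)
  with_seed(seed, {
    heldout <- vector("list", n_iter)
    for (lab in unique(labels)) {
      grp <- sample(ids[labels == lab])
      slot <- rep(seq_len(n_iter), length.out = length(grp))
      for (i in seq_len(n_iter))
        heldout[[i]] <- c(heldout[[i]], grp[slot == i])
    }
    lapply(seq_len(n_iter), function(i) {
      train_ids <- setdiff(ids, heldout[[i]])
      folds <- integer(0)
      for (lab in unique(labels)) {
        grp <- sample(train_ids[labels[train_ids] == lab])
        if (length(grp))
          folds[grp] <- rep(seq_len(k), length.out = length(grp))
      }
      structure(list(iteration = i, heldout = sort(heldout[[i]]),
                     folds = folds[sort(names(folds))], labels = labels),
                class = "split_plan")
    })
  })
}

#' Preprocess a list of pullbacks
#'
#' @param vois List of `polar_pullback` objects.
#' @param cfg A [preprocess_config()].
#' @param guidewire Passed to [preprocess_voi()].
#' @return List of lists of `aligned_frame` objects.
#' @export
preprocess_dataset <- function(vois, cfg = preprocess_config(),
                               guidewire = "annotation") {
  lapply(vois, preprocess_voi, cfg = cfg, guidewire = guidewire)
}

# Per-VOI sampler with an isolated seed derived from (base seed, VOI id), so
# plans do not depend on the order in which VOIs are processed.
sample_training_vois <- function(pp_vois, ids, cfg) {
  plans <- list()
  for (id in ids) {
    vcfg <- cfg
    vcfg$seed <- as.integer((cfg$seed + 7919 * (match(id, names(pp_vois)))) %%
                              .Machine$integer.max)
    plans[[id]] <- sample_frames(pp_vois[[id]], vcfg, voi_id = id)
  }
  plans
}

frames_from_plans <- function(pp_vois, plans) {
  out <- list()
  for (id in names(plans))
    out <- c(out, pp_vois[[id]][plans[[id]]$selected + 1L])
  out
}

all_frames <- function(pp_vois, ids) {
  out <- list()
  for (id in ids) out <- c(out, pp_vois[[id]])
  out
}

#' Train and evaluate one sampler model on one held-out rotation
#'
#' Applies the sampler to every training VOI, optionally grid-searches
#' segmentation hyperparameters by k-fold cross-validation over the split
#' plan's folds (three-way train / validation / test rotation within each
#' fold iteration; the best point maximises mean calcific F1 over test
#' folds), retrains on the full sampled training set for the mean number of
#' epochs the CV runs took, and evaluates on every frame of the held-out
#' VOIs.
#'
#' @param pp_vois Named list (VOI id -> list of `aligned_frame`) of
#'   preprocessed VOIs.
#' @param plan A `split_plan` from [make_split_plans()].
#' @param sampler_cfg A [sampler_config()].
#' @param seg_cfg A [seg_train_config()].
#' @param grid Optional list of `list(lr =, batch_size =)` candidates.
#' @param final_epochs Optional fixed final epoch count (skips the CV).
#' @param threshold Binarisation threshold for F1.
#' @return List: `metrics` (a `metrics_report` on the held-out set),
#'   `per_frame_ap` (held-out calcification frames), `plans` (per-VOI
#'   sampling plans), `cv` (fold results), `final_epochs`, `best_grid`,
#'   `model`.
#' @export
run_model <- function(pp_vois, plan, sampler_cfg, seg_cfg,
                      grid = NULL, final_epochs = NULL, threshold = 0.5) {
  stopifnot(inherits(plan, "split_plan"))
  if (is.null(names(pp_vois)))
    names(pp_vois) <- as.character(seq_along(pp_vois) - 1L)
  train_ids <- names(plan$folds)
  stopifnot(length(intersect(train_ids, plan$heldout)) == 0)  # no leakage
  plans <- sample_training_vois(pp_vois, train_ids, sampler_cfg)

  if (is.null(grid))
    grid <- list(list(lr = seg_cfg$lr, batch_size = seg_cfg$batch_size))
  k <- max(plan$folds)
  cv <- NULL
  best <- grid[[1L]]
  if (is.null(final_epochs)) {
    cv <- lapply(grid, function(g) {
      cfg_g <- seg_cfg; cfg_g$lr <- g$lr; cfg_g$batch_size <- g$batch_size
      fold_f1 <- fold_ep <- numeric(k)
      for (i in seq_len(k)) {
        test_fold <- i
        val_fold <- i %% k + 1L
        tr_ids <- train_ids[!plan$folds[train_ids] %in% c(test_fold, val_fold)]
        va_ids <- train_ids[plan$folds[train_ids] == val_fold]
        te_ids <- train_ids[plan$folds[train_ids] == test_fold]
        fit <- train_segmenter(frames_from_plans(pp_vois, plans[tr_ids]),
                               frames_from_plans(pp_vois, plans[va_ids]),
                               cfg_g)
        te_frames <- all_frames(pp_vois, te_ids)
        probs <- predict_probability(fit$model, te_frames)
        f1 <- f1_per_class(threshold_masks(probs, threshold),
                           lapply(te_frames, `[[`, "mask"))
        fold_f1[i] <- f1["calcific"]
        fold_ep[i] <- fit$record$stopped_epoch
      }
      list(grid = g, mean_f1 = mean(fold_f1), fold_f1 = fold_f1,
           mean_epochs = mean(fold_ep))
    })
    scores <- vapply(cv, `[[`, numeric(1), "mean_f1")
    best_i <- which.max(scores)
    best <- grid[[best_i]]
    final_epochs <- max(1L, as.integer(round(cv[[best_i]]$mean_epochs)))
  }

  cfg_best <- seg_cfg
  cfg_best$lr <- best$lr
  cfg_best$batch_size <- best$batch_size
  fit <- train_segmenter_fixed(frames_from_plans(pp_vois, plans),
                               cfg_best, final_epochs)

  ho_frames <- all_frames(pp_vois, plan$heldout)
  probs <- predict_probability(fit$model, ho_frames)
  masks <- lapply(ho_frames, `[[`, "mask")
  metrics <- metrics_report(probs, masks, threshold)
  per_frame_ap <- tryCatch(
    average_precision(probs, masks, per_frame = TRUE),
    error = function(e) numeric(0))
  list(metrics = metrics, per_frame_ap = per_frame_ap, plans = plans,
       cv = cv, final_epochs = final_epochs, best_grid = best,
       model = fit$model)
}

seven_model_grid <- function(ratios = c(1 / 2, 1 / 3, 1 / 10)) {
  specs <- list(list(name = "all", method = "all", ratio = 1))
  for (r in ratios)
    specs <- c(specs, list(list(name = sprintf("equal_%.3g", r),
                                method = "equal_spacing", ratio = r)))
  for (r in ratios)
    specs <- c(specs, list(list(name = sprintf("cluster_%.3g", r),
                                method = "clustering", ratio = r)))
  specs
}

#' The multi-model sampler comparison
#'
#' Trains, for every held-out rotation, one model per sampler branch (all
#' frames; equal spacing and clustering at each ratio — seven models at the
#' default three ratios) with identical split plans and segmentation seeds,
#' so the sampler is the only varying factor. Reports mean and standard
#' error of each metric across iterations.
#'
#' @param pp_vois Named list of preprocessed VOIs.
#' @param labels VOI labels aligned with `pp_vois`.
#' @param cfg An [experiment_config()].
#' @return List: `table` (data frame, one row per model: mean and SE of
#'   F1-calcific, F1-other, AP), `runs` (nested per-iteration results),
#'   `split_plans`.
#' @export
run_seven_model_comparison <- function(pp_vois, labels,
                                       cfg = experiment_config()) {
  if (is.null(names(pp_vois)))
    names(pp_vois) <- as.character(seq_along(pp_vois) - 1L)
  names(labels) <- names(pp_vois)
  plans <- make_split_plans(labels, cfg$n_iterations, cfg$cv_folds,
                            seed = cfg$master_seed)
  specs <- seven_model_grid(cfg$ratios)
  runs <- lapply(plans, function(pl) {
    lapply(specs, function(sp) {
      s_cfg <- cfg$sampler
      s_cfg$method <- sp$method
      s_cfg$ratio <- sp$ratio
      s_cfg$seed <- as.integer(cfg$master_seed + 131 * pl$iteration)
      g_cfg <- cfg$seg
      g_cfg$seed <- as.integer(cfg$master_seed + 977 * pl$iteration)
      run_model(pp_vois, pl, s_cfg, g_cfg, grid = cfg$grid,
                final_epochs = cfg$final_epochs)
    })
  })
  se <- function(x) sd(x) / sqrt(length(x))
  rows <- lapply(seq_along(specs), function(si) {
    f1c <- vapply(runs, function(r) r[[si]]$metrics$f1_calcific, numeric(1))
    f1o <- vapply(runs, function(r) r[[si]]$metrics$f1_other, numeric(1))
    ap <- vapply(runs, function(r) r[[si]]$metrics$ap, numeric(1))
    data.frame(model = specs[[si]]$name,
               f1_calcific = mean(f1c), f1_calcific_se = se(f1c),
               f1_other = mean(f1o), f1_other_se = se(f1o),
               ap = mean(ap), ap_se = se(ap))
  })
  list(table = do.call(rbind, rows), runs = runs, split_plans = plans)
}

#' The fewer-VOIs experiment
#'
#' Tests whether, for a fixed annotation budget (one-tenth of the training
#' frames), subsampling from all VOIs beats taking all frames from the first
#' few VOIs of a shuffled order. For each held-out rotation the budget is
#' filled by whole VOIs in shuffled order (the VOI that crosses the budget
#' is included whole); `n_shuffles` such models are trained and their
#' held-out APs compared to the one-tenth-clustered baseline with a
#' one-sample Wilcoxon test (alternative: shuffled models perform worse).
#'
#' @param pp_vois Named list of preprocessed VOIs.
#' @param labels VOI labels aligned with `pp_vois`.
#' @param cfg An [experiment_config()]; `ratio` for the budget and baseline
#'   is the last entry of `cfg$ratios` (one-tenth by default).
#' @param baseline_runs Optional list of per-iteration baseline results
#'   (clustered sampler at the budget ratio) to reuse; otherwise computed.
#' @return Per-iteration list: `shuffled_aps`, `baseline_ap`, `wilcoxon`
#'   (from [compare_models()]), `orders` (the shuffled VOI orders),
#'   `n_vois_used`.
#' @export
run_fewer_vois_experiment <- function(pp_vois, labels,
                                      cfg = experiment_config(),
                                      baseline_runs = NULL) {
  if (is.null(names(pp_vois)))
    names(pp_vois) <- as.character(seq_along(pp_vois) - 1L)
  names(labels) <- names(pp_vois)
  ratio <- cfg$ratios[length(cfg$ratios)]
  plans <- make_split_plans(labels, cfg$n_iterations, cfg$cv_folds,
                            seed = cfg$master_seed)
  shuffle_seeds <- with_seed(cfg$master_seed + 17L,
                             matrix(sample.int(.Machine$integer.max - 1L,
                                               cfg$n_iterations * cfg$n_shuffles),
                                    cfg$n_iterations))
  lapply(plans, function(pl) {
    it <- pl$iteration
    s_cfg <- cfg$sampler
    s_cfg$method <- "clustering"
    s_cfg$ratio <- ratio
    s_cfg$seed <- as.integer(cfg$master_seed + 131 * it)
    g_cfg <- cfg$seg
    g_cfg$seed <- as.integer(cfg$master_seed + 977 * it)
    base <- if (!is.null(baseline_runs)) baseline_runs[[it]]
            else run_model(pp_vois, pl, s_cfg, g_cfg, grid = cfg$grid,
                           final_epochs = cfg$final_epochs)
    train_ids <- names(pl$folds)
    sizes <- vapply(pp_vois[train_ids], length, integer(1))
    budget <- ceiling(ratio * sum(sizes))
    ho_frames <- all_frames(pp_vois, pl$heldout)
    ho_masks <- lapply(ho_frames, `[[`, "mask")
    shuffled <- lapply(seq_len(cfg$n_shuffles), function(s) {
      ord <- with_seed(shuffle_seeds[it, s], sample(train_ids))
      n_take <- which(cumsum(sizes[ord]) >= budget)[1L]
      if (is.na(n_take)) n_take <- length(ord)
      # a training set with no calcific pixels makes the weighted loss
      # degenerate; extend the prefix until a calcification VOI is included
      while (n_take < length(ord) &&
             !any(labels[ord[seq_len(n_take)]] == "calcification"))
        n_take <- n_take + 1L
      take <- ord[seq_len(n_take)]
      fr_cfg <- g_cfg
      fr_cfg$seed <- as.integer(shuffle_seeds[it, s] %% 1e6)
      fit <- train_segmenter_fixed(all_frames(pp_vois, take), fr_cfg,
                                   base$final_epochs)
      probs <- predict_probability(fit$model, ho_frames)
      list(ap = average_precision(probs, ho_masks)$ap, order = ord,
           n_vois_used = n_take)
    })
    aps <- vapply(shuffled, `[[`, numeric(1), "ap")
    list(shuffled_aps = aps,
         baseline_ap = base$metrics$ap,
         wilcoxon = compare_models(aps, mu = base$metrics$ap,
                                   alternative = "less"),
         orders = lapply(shuffled, `[[`, "order"),
         n_vois_used = vapply(shuffled, `[[`, integer(1), "n_vois_used"))
  })
}
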