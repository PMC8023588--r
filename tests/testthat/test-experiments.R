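test_that("split plans rotate every VOI through the held-out set once", {
  labels <- c(rep("normal", 4L), rep("calcification", 4L))
  names(labels) <- paste0("v", 1:8)
  plans <- make_split_plans(labels, n_iter = 4L, k = 5L, seed = 3L)
  expect_length(plans, 4L)
  held <- unlist(lapply(plans, `[[`, "heldout"))
  expect_setequal(held, names(labels))
  expect_identical(anyDuplicated(held), 0L)
  for (pl in plans) {
    # stratified: one of each label in every held-out pair
    expect_length(pl$heldout, 2L)
    expect_setequal(unname(labels[pl$heldout]), c("normal", "calcification"))
    # folds partition the training VOIs
    expect_setequal(names(pl$folds), setdiff(names(labels), pl$heldout))
    expect_true(all(pl$folds %in% 1:5))
  }
  # new seed: different but still valid plans
  plans2 <- make_split_plans(labels, n_iter = 4L, k = 5L, seed = 4L)
  expect_setequal(unlist(lapply(plans2, `[[`, "heldout")), names(labels))
  expect_false(identical(lapply(plans, `[[`, "heldout"),
                         lapply(plans2, `[[`, "heldout")))
  # determinism
  plans3 <- make_split_plans(labels, n_iter = 4L, k = 5L, seed = 3L)
  expect_identical(plans, plans3)
})

test_that("fold label balance stays within one VOI of the global ratio", {
  set.seed(5)
  labels <- c(rep("normal", 11L), rep("calcification", 14L))
  names(labels) <- paste0("v", seq_along(labels))
  plans <- make_split_plans(labels, n_iter = 4L, k = 5L, seed = 9L)
  for (pl in plans) {
    tr_labels <- labels[names(pl$folds)]
    for (lab in unique(labels)) {
      per_fold <- tabulate(pl$folds[tr_labels == lab], 5L)
      expect_lte(max(per_fold) - min(per_fold), 1L)
    }
  }
})

# Shared desk-scale dataset for the orchestration tests.
experiments_fixture <- local({
  env <- new.env()
  function() {
    if (is.null(env$pp)) {
      cfg <- phantom_config(
        n_alines = 64L, n_radial = 96L, n_frames = 10L,
        speckle_scale = 0.45, lumen_radius_mean = 14,
        lumen_radius_amplitude = 5, guidewire_width = 4L,
        lesion_params = list(depth_px = 6, thickness_px = 16,
                             z_drift = 0.015))
      vois <- generate_dataset(3, 5, seed = 71L,
                               n_frames_range = c(8L, 12L), config = cfg)
      env$pp <- preprocess_dataset(vois, preprocess_config(crop_depth = 48L))
      names(env$pp) <- as.character(seq_along(env$pp) - 1L)
      env$labels <- vapply(vois, `[[`, character(1), "voi_label")
      names(env$labels) <- names(env$pp)
    }
    env
  }
})

test_that("run_model keeps frames of held-out VOIs out of training", {
  fx <- experiments_fixture()
  plans <- make_split_plans(fx$labels, n_iter = 4L, k = 3L, seed = 1L)
  pl <- plans[[1]]
  s_cfg <- sampler_config(method = "equal_spacing", ratio = 1 / 2, seed = 1L)
  g_cfg <- seg_train_config(widths = c(2L, 4L), batch_size = 4L,
                            max_epochs = 6L, max_restarts = 0L, seed = 1L)
  res <- run_model(fx$pp, pl, s_cfg, g_cfg, final_epochs = 6L)
  # sampling plans exist exactly for the training VOIs
  expect_setequal(names(res$plans), names(pl$folds))
  expect_true(all(!names(res$plans) %in% pl$heldout))
  for (id in names(res$plans))
    expect_length(res$plans[[id]]$selected,
                  target_count(length(fx$pp[[id]]), 1 / 2))
  expect_s3_class(res$metrics, "metrics_report")
  expect_identical(res$final_epochs, 6L)
})

test_that("the inner CV selects hyperparameters and the epoch budget", {
  fx <- experiments_fixture()
  plans <- make_split_plans(fx$labels, n_iter = 4L, k = 3L, seed = 2L)
  pl <- plans[[1]]
  s_cfg <- sampler_config(method = "all", ratio = 1, seed = 1L)
  g_cfg <- seg_train_config(widths = c(2L, 2L), batch_size = 4L,
                            max_epochs = 5L, patience = 2L,
                            max_restarts = 0L, seed = 3L)
  grid <- list(list(lr = 1e-3, batch_size = 4L),
               list(lr = 1e-4, batch_size = 2L))
  res <- run_model(fx$pp, pl, s_cfg, g_cfg, grid = grid)
  expect_length(res$cv, 2L)
  expect_true(res$best_grid$lr %in% c(1e-3, 1e-4))
  scores <- vapply(res$cv, `[[`, numeric(1), "mean_f1")
  expect_identical(res$best_grid$lr, grid[[which.max(scores)]]$lr)
  expect_identical(res$final_epochs,
                   max(1L, as.integer(round(res$cv[[which.max(scores)]]$mean_epochs))))
})

test_that("the sampler-comparison grid covers the seven protocol branches", {
  specs <- octsubset:::seven_model_grid(c(1 / 2, 1 / 3, 1 / 10))
  expect_length(specs, 7L)
  expect_identical(specs[[1]]$method, "all")
  expect_identical(vapply(specs[2:4], `[[`, character(1), "method"),
                   rep("equal_spacing", 3L))
  expect_identical(vapply(specs[5:7], `[[`, character(1), "method"),
                   rep("clustering", 3L))
  expect_equal(vapply(specs[2:4], `[[`, numeric(1), "ratio"),
               c(1 / 2, 1 / 3, 1 / 10))
})

test_that("the fewer-VOIs budget rule takes whole VOIs until the budget", {
  fx <- experiments_fixture()
  ecfg <- experiment_config(
    n_iterations = 2L, cv_folds = 3L, n_shuffles = 2L,
    ratios = c(1 / 2),
    sampler = sampler_config(ae_epochs = 4L),
    seg = seg_train_config(widths = c(2L, 2L), batch_size = 4L,
                           max_epochs = 4L, max_restarts = 0L),
    final_epochs = 4L, master_seed = 5L)
  res <- run_fewer_vois_experiment(fx$pp, fx$labels, ecfg)
  expect_length(res, 2L)
  plans <- make_split_plans(fx$labels, 2L, 3L, seed = 5L)
  for (i in seq_along(res)) {
    it <- res[[i]]
    expect_length(it$shuffled_aps, 2L)
    expect_true(is.finite(it$baseline_ap))
    expect_identical(it$wilcoxon$method, "one-sample Wilcoxon")
    for (s in seq_along(it$orders)) {
      ord <- it$orders[[s]]
      n_used <- it$n_vois_used[s]
      sizes <- vapply(fx$pp[ord], length, integer(1))
      budget <- ceiling(0.5 * sum(vapply(fx$pp[ord], length, integer(1))))
      # the prefix reaches the budget; its predecessor does not
      expect_gte(sum(sizes[seq_len(n_used)]), budget)
      if (n_used > 1L &&
          any(fx$labels[ord[seq_len(n_used - 1L)]] == "calcification"))
        expect_lt(sum(sizes[seq_len(n_used - 1L)]), budget)
    }
    # every shuffle logs a full permutation of that iteration's training VOIs
    for (ord in it$orders)
      expect_setequal(ord, names(plans[[i]]$folds))
  }
})
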