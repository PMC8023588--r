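# Cached small fixtures: one preprocessed VOI and one trained autoencoder
# shared across tests in this file.
select_fixture <- local({
  env <- new.env()
  function() {
    if (is.null(env$pp)) {
      env$pp <- small_preprocessed_voi(n_frames = 12L, seed = 31L)
      env$cfg <- sampler_config(ae_epochs = 25L, ratio = 1 / 3, seed = 5L)
      env$fit <- train_autoencoder(env$pp, env$cfg)
    }
    env
  }
})

test_that("target_count implements the ceiling rule with a floor of one", {
  expect_identical(target_count(9, 1 / 3), 3L)
  expect_identical(target_count(10, 1 / 10), 1L)
  expect_identical(target_count(7, 1 / 2), 4L)    # ceil(3.5)
  expect_identical(target_count(1, 1 / 10), 1L)
  expect_identical(target_count(5, 1), 5L)
})

test_that("equal spacing walks the z-stack at the stride of the ratio", {
  expect_identical(equal_spacing_indices(9, 1 / 3)$selected, c(0L, 3L, 6L))
  expect_identical(equal_spacing_indices(5, 1)$selected, 0:4)
  expect_identical(equal_spacing_indices(10, 1 / 10)$selected, 0L)
  # stride-2 enumeration for ratio one-half on odd length
  expect_identical(equal_spacing_indices(7, 1 / 2)$selected, c(0L, 2L, 4L, 6L))
})

test_that("selector cardinality equals target_count for every method/ratio", {
  set.seed(11)
  for (rep in 1:40) {
    n <- sample(1:200, 1)
    ratio <- sample(c(1 / 2, 1 / 3, 1 / 10, 0.3, 0.45, 0.8, 1), 1)
    plan <- equal_spacing_indices(n, ratio)
    expect_identical(length(plan$selected), target_count(n, ratio))
    expect_true(all(plan$selected >= 0 & plan$selected < n))
    expect_false(anyDuplicated(plan$selected) > 0)
  }
})

test_that("PCA keeps the smallest component set reaching the variance goal", {
  set.seed(21)
  # exact line in R^5: one component carries all variance
  t_ <- rnorm(12)
  line <- outer(t_, c(1, 2, -1, 0.5, 3))
  red <- reduce_pca(line, 0.95)
  expect_identical(ncol(red$matrix), 1L)
  # random matrices: cumulative ratio >= 0.95, and m-1 components < 0.95
  for (rep in 1:10) {
    m <- matrix(rnorm(10 * 64), 10, 64)
    ev <- prcomp(m, center = TRUE)$sdev^2
    ratio <- cumsum(ev) / sum(ev)
    red <- reduce_pca(m, 0.95)
    k <- ncol(red$matrix)
    expect_gte(ratio[k], 0.95)
    if (k > 1) expect_lt(ratio[k - 1], 0.95)
    expect_lte(k, nrow(m) - 1L)
  }
  # variance = 1 keeps the full rank of the centred matrix
  m <- matrix(rnorm(6 * 4), 6, 4)
  expect_identical(ncol(reduce_pca(m, 1)$matrix), 4L)
  # degenerate: identical frames
  expect_warning(red0 <- reduce_pca(matrix(1, 5, 8), 0.95), "zero variance")
  expect_identical(ncol(red0$matrix), 1L)
})

brute_force_kmedoids <- function(X, k) {
  D <- as.matrix(dist(X))
  n <- nrow(X)
  best <- Inf
  for (set in asplit(utils::combn(n, k), 2)) {
    cost <- sum(apply(D[set, , drop = FALSE], 2, min))
    if (cost < best) best <- cost
  }
  best
}

test_that("PAM matches the exhaustive k-medoids optimum on small instances", {
  # worked 1-D example: two tight pairs
  km <- k_medoids(matrix(c(0, 1, 10, 11)), 2)
  expect_identical(km$total_cost, 2)
  # one medoid per tight pair
  expect_true(km$medoid_frame_ids[1] %in% c(0L, 1L))
  expect_true(km$medoid_frame_ids[2] %in% c(2L, 3L))
  # k = n: zero cost, every point its own medoid
  kmn <- k_medoids(matrix(rnorm(5)), 5)
  expect_identical(kmn$total_cost, 0)
  expect_identical(kmn$medoid_frame_ids, 0:4)
  # k = 1: the 1-D medoid is the element minimising summed distance
  x <- matrix(c(0, 2, 3, 9))
  km1 <- k_medoids(x, 1)
  costs <- colSums(abs(outer(x[, 1], x[, 1], "-")))
  expect_identical(km1$medoid_frame_ids, which.min(costs) - 1L)
  # randomized: PAM never beats brute force and matches it almost always
  set.seed(33)
  matches <- 0L
  for (rep in 1:30) {
    n <- sample(4:8, 1); k <- sample(1:3, 1)
    X <- matrix(rnorm(n * 2), n)
    pam_cost <- k_medoids(X, k)$total_cost
    opt <- brute_force_kmedoids(X, k)
    expect_gte(pam_cost, opt - 1e-9)
    if (pam_cost <= opt + 1e-9) matches <- matches + 1L
  }
  expect_gte(matches, 27L)   # ~90% on this small draw; the 100-instance
                             # acceptance check enforces the 95% bar
  expect_error(k_medoids(matrix(rnorm(3)), 4), "k must be in")
})

test_that("PAM agrees with the cluster package on moderate instances", {
  skip_if_not_installed("cluster")
  set.seed(44)
  for (rep in 1:5) {
    X <- matrix(rnorm(30 * 3), 30)
    k <- sample(2:5, 1)
    ours <- k_medoids(X, k)
    ref <- cluster::pam(X, k)
    ref_cost <- sum(vapply(seq_len(30), function(i)
      min(sqrt(colSums((t(X[ref$id.med, , drop = FALSE]) - X[i, ])^2))),
      numeric(1)))
    # both are local optima of the same objective; neither should be
    # meaningfully better
    expect_lt(abs(ours$total_cost - ref_cost) / ref_cost, 0.05)
  }
})

test_that("cluster assignments go to the nearest medoid and are non-empty", {
  set.seed(55)
  X <- matrix(rnorm(20 * 2), 20)
  km <- k_medoids(X, 4)
  D <- as.matrix(dist(X))
  med_rows <- km$medoid_frame_ids + 1L
  for (i in seq_len(20)) {
    d_i <- D[med_rows, i]
    expect_equal(unname(d_i[km$assignments[i]]), min(d_i))
  }
  expect_true(all(tabulate(km$assignments, 4) > 0))
  expect_lte(km$total_cost, km$build_cost + 1e-12)
})

test_that("autoencoder training is deterministic and reduces the loss", {
  fx <- select_fixture()
  fit <- fx$fit
  expect_length(fit$record$epoch_loss, 25L)
  # same seed twice: identical losses
  fit2 <- train_autoencoder(fx$pp, fx$cfg)
  expect_identical(fit$record$epoch_loss, fit2$record$epoch_loss)
  # broad loss decrease with at most a few transient rises
  el <- fit$record$epoch_loss
  expect_lt(el[25], el[1])
  rises <- sum(diff(el) > 0)
  expect_lte(rises, ceiling(0.05 * length(el)) + 1L)
  expect_identical(fit$record$final_mse, fit2$record$final_mse)
})

test_that("single-precision training engine matches the R reference", {
  fx <- select_fixture()
  cfg <- fx$cfg
  cfg$ae_epochs <- 4L
  a <- train_autoencoder(fx$pp[1:6], cfg)
  b <- octsubset:::ae_train_reference(fx$pp[1:6], cfg)
  expect_equal(a$record$epoch_loss, b$record$epoch_loss, tolerance = 1e-5)
  expect_equal(a$record$final_mse, b$record$final_mse, tolerance = 1e-4)
})

test_that("bottleneck features are pure functions of the frames", {
  fx <- select_fixture()
  frames <- c(fx$pp[1:3], fx$pp[1])   # duplicate frame 1 at the end
  feats <- extract_bottleneck_features(fx$fit$model, frames)
  expect_identical(nrow(feats$matrix), 4L)
  expect_equal(feats$matrix[1, ], feats$matrix[4, ])
  f1 <- extract_bottleneck_features(fx$fit$model, fx$pp[1])
  expect_identical(dim(f1$matrix), c(1L, ncol(feats$matrix)))
  # flatten mode keeps the full bottleneck dimensionality
  ffl <- extract_bottleneck_features(fx$fit$model, fx$pp[1], pool = "flatten")
  expect_gt(ncol(ffl$matrix), ncol(f1$matrix))
})

test_that("clustering sampler honours the cardinality and trivial cases", {
  fx <- select_fixture()
  # ratio 1 selects everything without clustering
  cfg1 <- fx$cfg; cfg1$ratio <- 1
  expect_identical(clustering_sample(fx$pp, cfg1)$selected, 0:11)
  # three identical frames at ratio 1/3: any single frame
  cfg3 <- fx$cfg; cfg3$ratio <- 1 / 3; cfg3$ae_epochs <- 5L
  same <- fx$pp[c(1, 1, 1)]
  expect_warning(plan <- clustering_sample(same, cfg3), "zero variance")
  expect_length(plan$selected, 1L)
  # standard path: correct count, sorted, within range
  plan2 <- clustering_sample(fx$pp, fx$cfg)
  expect_length(plan2$selected, target_count(12L, fx$cfg$ratio))
  expect_identical(plan2$selected, sort(plan2$selected))
  expect_true(all(plan2$selected %in% 0:11))
  expect_identical(plan2$details$pca_dim, ncol(
    reduce_pca(extract_bottleneck_features(fx$fit$model, fx$pp),
               fx$cfg$pca_variance)$matrix))
})

test_that("samplers leave the caller's RNG stream untouched", {
  fx <- select_fixture()
  set.seed(99)
  before <- .Random.seed
  invisible(sample_frames(fx$pp, fx$cfg, voi_id = "a"))
  expect_identical(.Random.seed, before)
  # plans are a function of (frames, config) only, not processing order
  p1 <- clustering_sample(fx$pp, fx$cfg, voi_id = "a")
  invisible(clustering_sample(fx$pp[1:6], fx$cfg, voi_id = "b"))
  p2 <- clustering_sample(fx$pp, fx$cfg, voi_id = "a")
  expect_identical(p1$selected, p2$selected)
})

test_that("clustering-selected frames are more feature-diverse than equally spaced", {
  wins <- 0L
  for (s in 1:10) {
    pb <- generate_voi(archetype_voi_config(300L + s),
                       archetypes = cluster_archetypes())
    pp <- preprocess_voi(pb, small_preprocess_config())
    cfg <- sampler_config(ratio = 1 / 10, ae_epochs = 30L, seed = s)
    fit <- train_autoencoder(pp, cfg)
    feats <- reduce_pca(extract_bottleneck_features(fit$model, pp),
                        cfg$pca_variance)
    cl <- k_medoids(feats, target_count(length(pp), cfg$ratio))
    eq <- equal_spacing_indices(length(pp), cfg$ratio)$selected
    dmean <- function(idx) mean(dist(feats$matrix[idx + 1L, , drop = FALSE]))
    if (dmean(sort(cl$medoid_frame_ids)) >= dmean(eq)) wins <- wins + 1L
  }
  expect_gte(wins, 7L)
})

test_that("sampling plans serialise to JSON and back", {
  dir <- withr::local_tempdir()
  plan <- equal_spacing_indices(9, 1 / 3, voi_id = "voi7")
  path <- file.path(dir, "plan.json")
  write_plan(plan, path)
  rt <- read_plan(path)
  expect_identical(rt$selected, plan$selected)
  expect_identical(rt$method, plan$method)
  expect_identical(rt$voi_id, "voi7")
})
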