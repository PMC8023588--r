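test_that("pixel-pooled F1 matches hand computations", {
  y <- matrix(c(1, 1, 0, 0), 2)
  expect_equal(unname(f1_per_class(y, y)), c(1, 1))
  # all-other prediction against truth with positives
  expect_equal(unname(f1_per_class(matrix(0L, 2, 2), y)["calcific"]), 0)
  # TP = 2, FP = 1, FN = 1 toy
  pred <- matrix(c(1, 1, 1, 0), 2)
  true <- matrix(c(1, 1, 0, 1), 2)
  expect_equal(unname(f1_per_class(pred, true)["calcific"]), 2 * 2 / 6)
  # symmetry under simultaneous class swap
  f <- f1_per_class(pred, true)
  fs <- f1_per_class(1L - pred, 1L - true)
  expect_equal(unname(f["calcific"]), unname(fs["other"]))
  expect_equal(unname(f["other"]), unname(fs["calcific"]))
})

test_that("average precision reproduces the hand-stepped PR curve", {
  # 4-pixel worked case
  probs <- matrix(c(0.9, 0.8, 0.7, 0.1), 1)
  labels <- matrix(c(1, 0, 1, 0), 1)
  res <- average_precision(probs, labels)
  expect_equal(res$ap, 1 * 0.5 + (2 / 3) * 0.5)
  expect_true(all(diff(res$pr_curve$recall) >= 0))
  # perfect ranking
  expect_equal(average_precision(matrix(c(0.9, 0.8, 0.2, 0.1), 1),
                                 matrix(c(1, 1, 0, 0), 1))$ap, 1)
  # label-independent scores: AP approximately the positive fraction
  set.seed(6)
  q <- 0.15
  lab <- matrix(rbinom(10000, 1, q), 100)
  sc <- matrix(runif(10000), 100)
  expect_lt(abs(average_precision(sc, lab)$ap - q), 0.02)
})

test_that("AP is invariant to monotone transforms and handles normal frames", {
  set.seed(7)
  probs <- list(matrix(runif(64), 8), matrix(runif(64), 8))
  masks <- list(matrix(rbinom(64, 1, 0.3), 8), matrix(0L, 8, 8))
  # second frame has no positives: excluded by default
  res <- average_precision(probs, masks)
  expect_identical(res$n_frames_included, 1L)
  expect_error(average_precision(probs, masks, exclude_normal = FALSE),
               "undefined")
  expect_error(average_precision(probs[2], masks[2]), "undefined")
  # monotone transform of the scores leaves AP unchanged
  res2 <- average_precision(lapply(probs, function(p) p^3), masks)
  expect_equal(res$ap, res2$ap)
  # per-frame mode scores each calcification frame independently
  masks2 <- list(matrix(rbinom(64, 1, 0.3), 8), matrix(rbinom(64, 1, 0.3), 8))
  pf <- average_precision(probs, masks2, per_frame = TRUE)
  expect_length(pf, 2L)
  expect_equal(unname(pf[1]), average_precision(probs[1], masks2[1])$ap)
})

test_that("calcification attributes recover the phantom geometry", {
  # empty mask: all zeros
  z <- calc_attributes(matrix(0L, 50, 40))
  expect_equal(unclass(z)[c("angle_deg", "depth_mm", "thickness_mm")],
               list(angle_deg = 0, depth_mm = 0, thickness_mm = 0))
  # full-circumference mask
  full <- calc_attributes(matrix(1L, 50, 40))
  expect_equal(full$angle_deg, 360)
  # synthetic lesion: arc 90 deg, depth 20 px, thickness 30 px
  nA <- 360L
  mask <- matrix(0L, 200, nA)
  mask[21:50, 1:90] <- 1L
  at <- calc_attributes(mask, pixel_pitch_mm = 1, deg_per_aline = 1)
  expect_equal(at$angle_deg, 90)
  expect_equal(at$depth_mm, 20)
  expect_equal(at$thickness_mm, 30)
  # phantom round trip through alignment: tolerance one A-line / one pixel
  cfg <- small_phantom_config(n_frames = 1L, seed = 17L, speckle_scale = 0,
                              guidewire_width = 0L)
  cfg$lesion_params <- utils::modifyList(
    cfg$lesion_params, list(arc_extent_deg = 90, depth_px = 20,
                            thickness_px = 30, z_drift = 0))
  pb <- generate_voi(cfg)
  al <- pixel_shift_align(pb$frames[[1]], pb$masks[[1]], pb$lumen[[1]])
  at2 <- calc_attributes(al$mask, pixel_pitch_mm = 1,
                         deg_per_aline = 360 / ncol(al$mask))
  expect_lt(abs(at2$angle_deg - 90), 2 * 360 / ncol(al$mask) + 1e-9)
  expect_lt(abs(at2$depth_mm - 20), 1 + 1e-9)
  expect_lt(abs(at2$thickness_mm - 30), 1 + 1e-9)
})

test_that("Bland-Altman bias and limits behave on constructed pairs", {
  x <- c(1, 2, 3, 4, 5)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_lower, 0)
  expect_equal(ba0$loa_upper, 0)
  ba5 <- bland_altman(x + 5, x)
  expect_equal(ba5$bias, 5)
  expect_equal(ba5$sd, 0)
  # zero-mean differences: bias within 1.96 sd/sqrt(n) of zero
  set.seed(8)
  d <- rnorm(400)
  ba <- bland_altman(d + 10, rep(10, 400))
  expect_lt(abs(ba$bias), 1.96 * ba$sd / sqrt(400))
  # data-frame interface
  df1 <- data.frame(angle = c(90, 100), depth = c(0.1, 0.2))
  tab <- bland_altman(df1, df1)
  expect_identical(tab$attribute, c("angle", "depth"))
  expect_equal(tab$bias, c(0, 0))
})

test_that("model comparison tests cover degenerate and standard cases", {
  # identical vectors: t = 0, p = 1
  a <- c(0.5, 0.6, 0.7, 0.8, 0.9)
  r0 <- compare_models(a, a)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # constant positive difference: exact sign-flip fallback, one-sided
  r1 <- compare_models(a + 0.1, a, alternative = "greater")
  expect_identical(r1$method, "exact sign-flip permutation")
  expect_lt(r1$p_value, 0.05)
  expect_equal(r1$p_value, 0.5^5)
  # ordinary paired t-test
  set.seed(9)
  x <- runif(20); y <- x - rnorm(20, 0.2, 0.05)
  r2 <- compare_models(x, y)
  expect_identical(r2$method, "paired t-test")
  expect_equal(r2$p_value,
               t.test(x, y, paired = TRUE)$p.value)
  # one-sample Wilcoxon against a baseline
  r3 <- compare_models(runif(10, 0.3, 0.5), mu = 0.7, alternative = "less")
  expect_identical(r3$method, "one-sample Wilcoxon")
  expect_lt(r3$p_value, 0.05)
})

test_that("simulated paired-test power matches the analytic value", {
  # shift alternative d ~ N(0.5, 1), n = 10, alpha = 0.05 (two-sided)
  n <- 10L; delta <- 0.5; alpha <- 0.05
  analytic <- power.t.test(n = n, delta = delta, sd = 1,
                           sig.level = alpha, type = "one.sample")$power
  set.seed(10)
  rej <- 0L
  reps <- 1000L
  for (i in seq_len(reps)) {
    d <- rnorm(n, delta, 1)
    base <- runif(n)
    if (compare_models(base + d, base)$p_value < alpha) rej <- rej + 1L
  }
  expect_lt(abs(rej / reps - analytic), 0.05)
})

test_that("metrics reports serialise to JSON with PR curve CSV", {
  dir <- withr::local_tempdir()
  set.seed(11)
  probs <- list(matrix(runif(64), 8))
  masks <- list(matrix(rbinom(64, 1, 0.3), 8))
  rep_ <- metrics_report(probs, masks)
  jpath <- file.path(dir, "metrics.json")
  cpath <- file.path(dir, "pr.csv")
  write_metrics(rep_, jpath, cpath)
  back <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_equal(back$ap, rep_$ap)
  expect_equal(nrow(utils::read.csv(cpath)), nrow(rep_$pr_curve))
})
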