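#' Pixel-level per-class F1 scores
#'
#' F1 = 2TP / (2TP + FP + FN) per class, pooled over all pixels of all
#' frames in the evaluation set. When a class has no positives in either
#' prediction or truth the score is 1 (perfect agreement on an absent
#' class).
#'
#' @param pred_masks,true_masks Binary matrices or lists thereof
#'   (1 = calcific).
#' @return Named numeric `c(calcific =, other =)`.
#' @export
f1_per_class <- function(pred_masks, true_masks) {
  if (is.matrix(pred_masks)) pred_masks <- list(pred_masks)
  if (is.matrix(true_masks)) true_masks <- list(true_masks)
  stopifnot(length(pred_masks) == length(true_masks))
  p <- unlist(pred_masks, use.names = FALSE)
  y <- unlist(true_masks, use.names = FALSE)
  stopifnot(length(p) == length(y))
  f1_one <- function(pv, yv) {
    tp <- sum(pv & yv); fp <- sum(pv & !yv); fn <- sum(!pv & yv)
    den <- 2 * tp + fp + fn
    if (den == 0) 1 else 2 * tp / den
  }
  c(calcific = f1_one(p == 1, y == 1), other = f1_one(p == 0, y == 0))
}

ap_from_scores <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  npos <- sum(y)
  if (npos == 0) stop("average precision undefined: no positive pixels")
  cum_tp <- cumsum(y)
  cum_pp <- seq_along(y)
  # evaluate at unique-threshold boundaries so tied scores share one point
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cum_tp[keep]; pp <- cum_pp[keep]
  precision <- tp / pp
  recall <- tp / npos
  ap <- sum(diff(c(0, recall)) * precision)
  list(ap = ap, pr_curve = data.frame(recall = recall, precision = precision))
}

#' Average precision (area under the precision--recall curve)
#'
#' Ranks pixels by predicted probability and accumulates
#' `sum((R_i - R_{i-1}) * P_i)` over the stepwise PR curve. Frames with no
#' calcific pixels make precision--recall undefined; by default they are
#' excluded (as frames from normal volumes are in practice). In pooled mode
#' all included frames' pixels form one ranking; in per-frame mode each
#' calcification-containing frame is scored independently.
#'
#' @param prob_maps,true_masks Probability and binary-mask matrices, or
#'   lists thereof.
#' @param exclude_normal Drop frames whose mask has no positive pixel. When
#'   `FALSE` and such frames are present (or nothing remains), an error is
#'   raised.
#' @param per_frame Return one AP per included frame instead of a pooled AP.
#' @return Pooled mode: list with `ap`, `pr_curve` (data frame of recall /
#'   precision points) and `n_frames_included`. Per-frame mode: numeric
#'   vector of APs (named by 0-based frame index).
#' @export
average_precision <- function(prob_maps, true_masks, exclude_normal = TRUE,
                              per_frame = FALSE) {
  if (is.matrix(prob_maps)) prob_maps <- list(prob_maps)
  if (is.matrix(true_masks)) true_masks <- list(true_masks)
  stopifnot(length(prob_maps) == length(true_masks))
  has_pos <- vapply(true_masks, function(m) sum(m) > 0, logical(1))
  if (exclude_normal) {
    keep <- which(has_pos)
  } else {
    if (!all(has_pos))
      stop("average precision undefined: frames without positive pixels ",
           "present and exclude_normal = FALSE")
    keep <- seq_along(true_masks)
  }
  if (length(keep) == 0)
    stop("average precision undefined: no calcification-containing frames")
  if (per_frame) {
    aps <- vapply(keep, function(i)
      ap_from_scores(as.numeric(prob_maps[[i]]),
                     as.numeric(true_masks[[i]]))$ap, numeric(1))
    names(aps) <- keep - 1L
    return(aps)
  }
  scores <- unlist(prob_maps[keep], use.names = FALSE)
  labels <- unlist(true_masks[keep], use.names = FALSE)
  res <- ap_from_scores(scores, labels)
  res$n_frames_included <- length(keep)
  res
}

#' Full segmentation metrics report
#'
#' Per-class F1 (pooled over all frames), average precision with
#' normal-frame exclusion, and the PR curve.
#'
#' @param prob_maps List of probability matrices.
#' @param true_masks List of binary masks.
#' @param threshold Binarisation threshold for the F1 scores.
#' @return A `metrics_report` list: `f1_calcific`, `f1_other`, `ap`,
#'   `pr_curve`, `n_frames_included`.
#' @export
metrics_report <- function(prob_maps, true_masks, threshold = 0.5) {
  f1 <- f1_per_class(threshold_masks(prob_maps, threshold), true_masks)
  ap <- average_precision(prob_maps, true_masks, exclude_normal = TRUE)
  structure(list(f1_calcific = unname(f1["calcific"]),
                 f1_other = unname(f1["other"]),
                 ap = ap$ap, pr_curve = ap$pr_curve,
                 n_frames_included = ap$n_frames_included),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> F1-calcific %.3f | F1-other %.3f | AP %.3f (%d frames)\n",
    x$f1_calcific, x$f1_other, x$ap, x$n_frames_included))
  invisible(x)
}

#' Clinical calcification attributes of a segmentation mask
#'
#' Computed on an aligned polar mask (lumen at row 1): angle is the
#' circumferential arc subtended by A-lines containing any calcific pixel;
#' depth is the smallest radial distance from the lumen to the lesion front
#' border; thickness is the mean radial lesion extent over the involved
#' A-lines. An empty mask yields all zeros.
#'
#' @param mask Binary matrix (rows = radius from lumen, cols = A-lines).
#' @param pixel_pitch_mm Radial pixel pitch in millimetres.
#' @param deg_per_aline Degrees per A-line; default `360 / ncol(mask)`.
#' @return A `calc_attributes` list: `angle_deg`, `depth_mm`,
#'   `thickness_mm`.
#' @export
calc_attributes <- function(mask, pixel_pitch_mm = 0.005,
                            deg_per_aline = NULL) {
  if (is.null(deg_per_aline)) deg_per_aline <- 360 / ncol(mask)
  cols <- which(colSums(mask) > 0)
  if (length(cols) == 0)
    return(structure(list(angle_deg = 0, depth_mm = 0, thickness_mm = 0),
                     class = "calc_attributes"))
  firsts <- vapply(cols, function(j) which(mask[, j] == 1)[1L], numeric(1))
  lasts <- vapply(cols, function(j) max(which(mask[, j] == 1)), numeric(1))
  structure(list(
    angle_deg = length(cols) * deg_per_aline,
    depth_mm = (min(firsts) - 1) * pixel_pitch_mm,
    thickness_mm = mean(lasts - firsts + 1) * pixel_pitch_mm
  ), class = "calc_attributes")
}

#' Bland--Altman agreement analysis
#'
#' Mean difference (bias) and 95% limits of agreement
#' (bias +/- 1.96 * sd of differences) between paired measurements.
#'
#' @param pred,truth Numeric vectors of paired measurements, or data frames
#'   of attribute columns compared column-wise.
#' @return For vectors: list with `bias`, `sd`, `loa_lower`, `loa_upper`,
#'   `n`. For data frames: a data frame with one row per attribute.
#' @export
bland_altman <- function(pred, truth) {
  if (is.data.frame(pred)) {
    stopifnot(is.data.frame(truth), identical(names(pred), names(truth)))
    rows <- lapply(names(pred), function(nm) {
      b <- bland_altman(pred[[nm]], truth[[nm]])
      data.frame(attribute = nm, bias = b$bias, sd = b$sd,
                 loa_lower = b$loa_lower, loa_upper = b$loa_upper, n = b$n)
    })
    return(do.call(rbind, rows))
  }
  stopifnot(length(pred) == length(truth), length(pred) >= 2)
  d <- pred - truth
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, sd = s,
       loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
       n = length(d))
}

#' Compare model performance across frames or against a baseline
#'
#' With two paired vectors of per-frame average precisions, runs a paired
#' t-test; when the paired differences are constant (zero variance) the
#' t-test is degenerate and an exact sign-flip permutation test is used
#' instead. With a single vector and `mu`, runs a one-sample Wilcoxon
#' signed-rank test against the baseline value.
#'
#' @param ap_a Per-frame AP vector of model A (or of the shuffled models in
#'   the one-sample case).
#' @param ap_b Optional paired per-frame AP vector of model B.
#' @param mu Baseline value for the one-sample Wilcoxon test.
#' @param alternative `"two.sided"`, `"greater"` or `"less"` (for the paired
#'   test, the alternative refers to `mean(ap_a - ap_b)`).
#' @return List with `method`, `statistic`, `p_value`, `estimate` (mean
#'   difference or median), `n`.
#' @export
compare_models <- function(ap_a, ap_b = NULL, mu = NULL,
                           alternative = "two.sided") {
  if (!is.null(ap_b)) {
    stopifnot(length(ap_a) == length(ap_b), length(ap_a) >= 2)
    d <- ap_a - ap_b
    n <- length(d)
    if (sd(d) == 0) {
      if (all(d == 0))
        return(list(method = "paired t-test", statistic = 0, p_value = 1,
                    estimate = 0, n = n))
      # exact sign-flip permutation: all differences share one sign and
      # magnitude, so only the all-plus / all-minus flips are as extreme
      p1 <- 0.5^n
      p <- switch(alternative,
                  two.sided = min(1, 2 * p1),
                  greater = if (d[1] > 0) p1 else 1 - p1,
                  less = if (d[1] < 0) p1 else 1 - p1)
      return(list(method = "exact sign-flip permutation", statistic = NA,
                  p_value = p, estimate = mean(d), n = n))
    }
    tt <- t.test(ap_a, ap_b, paired = TRUE, alternative = alternative)
    list(method = "paired t-test", statistic = unname(tt$statistic),
         p_value = tt$p.value, estimate = unname(tt$estimate), n = n)
  } else {
    stopifnot(!is.null(mu), length(ap_a) >= 1)
    wt <- suppressWarnings(wilcox.test(ap_a, mu = mu,
                                       alternative = alternative))
    list(method = "one-sample Wilcoxon", statistic = unname(wt$statistic),
         p_value = wt$p.value, estimate = median(ap_a), n = length(ap_a))
  }
}
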