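#' Configuration for a synthetic polar-domain IVOCT pullback
#'
#' Defines the geometry, noise and lesion parameters used by
#' [generate_voi()]. The defaults emulate the statistical structure of a
#' clinical coronary pullback: eccentric, slowly precessing lumen; a
#' guidewire shadow a few degrees wide; multiplicative speckle on an
#' exponentially attenuating tissue profile; and (for calcification volumes)
#' a signal-poor lesion with a sharply delineated front border whose arc,
#' depth and thickness drift smoothly along the pullback axis.
#'
#' @param n_alines Number of A-lines (angular samples) per frame.
#' @param n_radial Number of radial samples per frame; must comfortably
#'   exceed the downstream 200-pixel crop.
#' @param n_frames Number of contiguous frames in the volume of interest.
#' @param voi_label `"calcification"` or `"normal"` (no lesion, empty masks).
#' @param lumen_radius_mean,lumen_radius_amplitude Mean lumen offset and
#'   eccentricity amplitude, in radial pixels.
#' @param guidewire_width Width of the guidewire shadow, in A-lines.
#' @param lesion_params Named list: `arc_center_deg`, `arc_extent_deg`,
#'   `depth_px` (front border distance from the lumen), `thickness_px`
#'   (radial extent), and `z_drift` (per-frame drift scale, radians/frame
#'   for the arc centre and relative units for the sizes).
#' @param speckle_scale Speckle mixing weight in `[0, 1]`; 0 disables noise.
#' @param seed Integer seed; fully determines the generated volume.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(n_alines = 496L,
                           n_radial = 400L,
                           n_frames = 50L,
                           voi_label = c("calcification", "normal"),
                           lumen_radius_mean = 60,
                           lumen_radius_amplitude = 25,
                           guidewire_width = 16L,
                           lesion_params = list(),
                           speckle_scale = 0.6,
                           seed = 1L) {
  voi_label <- match.arg(voi_label)
  lp <- utils::modifyList(list(
    arc_center_deg = 120,
    arc_extent_deg = 130,
    depth_px = 25,
    thickness_px = 110,
    z_drift = 0.03
  ), lesion_params)
  cfg <- list(
    n_alines = as.integer(n_alines), n_radial = as.integer(n_radial),
    n_frames = as.integer(n_frames), voi_label = voi_label,
    lumen_radius_mean = lumen_radius_mean,
    lumen_radius_amplitude = lumen_radius_amplitude,
    guidewire_width = as.integer(guidewire_width),
    lesion_params = lp, speckle_scale = speckle_scale,
    seed = as.integer(seed)
  )
  stopifnot(cfg$n_alines > 0, cfg$n_radial > 0, cfg$n_frames > 0,
            cfg$guidewire_width >= 0, cfg$speckle_scale >= 0,
            lp$arc_extent_deg > 0, lp$arc_extent_deg <= 360,
            lp$depth_px >= 0, lp$thickness_px > 0)
  max_reach <- lumen_radius_mean + lumen_radius_amplitude +
    lp$depth_px + lp$thickness_px
  if (cfg$voi_label == "calcification" && max_reach >= cfg$n_radial)
    stop("lesion geometry exceeds image bounds: lumen + depth + thickness = ",
         max_reach, " >= n_radial = ", cfg$n_radial)
  if (lumen_radius_mean + lumen_radius_amplitude >= cfg$n_radial)
    stop("lumen geometry exceeds image bounds")
  class(cfg) <- "phantom_config"
  cfg
}

# Smooth per-frame drift track: random-walk increments filtered with a short
# moving average so neighbouring frames stay correlated.
smooth_track <- function(n, scale) {
  if (n == 1L) return(0)
  steps <- rnorm(n, 0, scale)
  track <- cumsum(steps)
  if (n >= 5L) track <- as.numeric(stats::filter(track, rep(1 / 5, 5),
                                                 sides = 2, circular = TRUE))
  track - track[1L]
}

#' Generate one synthetic polar IVOCT volume of interest
#'
#' Produces an ordered stack of polar-domain `(r, theta)` frames with ground
#' truth: per-frame lumen traces (0-based radial offset of the first tissue
#' pixel per A-line), guidewire-shadow A-line indices (0-based), and binary
#' calcification masks. Calcific regions are signal-poor with a sharp
#' intensity step at the front border, and all lesion attributes drift
#' smoothly from frame to frame so the stack is z-correlated. Output is fully
#' determined by `config$seed`.
#'
#' @param config A [phantom_config()].
#' @param archetypes Optional list of `lesion_params`-like lists. When given,
#'   the frame range is split into `length(archetypes)` contiguous blocks and
#'   block `i` uses lesion morphology `archetypes[[i]]` (used to plant known
#'   cluster structure for selector tests). An optional `weights` attribute
#'   sets relative block lengths.
#' @return A `polar_pullback` list with elements `frames` (list of
#'   `n_radial x n_alines` matrices in `[0, 1]`), `lumen` (list of 0-based
#'   integer vectors), `guidewire` (list of 0-based A-line index vectors),
#'   `masks` (list of binary matrices), `voi_label`, and `config`.
#' @export
generate_voi <- function(config, archetypes = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(config$seed, generate_voi_impl(config, archetypes))
}

generate_voi_impl <- function(config, archetypes = NULL) {
  nA <- config$n_alines; nR <- config$n_radial; nz <- config$n_frames
  theta <- (seq_len(nA) - 1L) / nA * 2 * pi
  calc <- config$voi_label == "calcification"

  # per-frame smooth tracks
  ph <- runif(1, 0, 2 * pi)                       # lumen eccentricity phase
  ph_track <- ph + smooth_track(nz, 0.05)
  lum_mean_track <- config$lumen_radius_mean * (1 + 0.1 * sin(
    seq_len(nz) / nz * 2 * pi + runif(1, 0, 2 * pi)))
  gw_center <- runif(1, 0, 2 * pi) + smooth_track(nz, 0.02)

  # lesion archetype per frame (contiguous blocks)
  if (!is.null(archetypes)) {
    k <- length(archetypes)
    wts <- attr(archetypes, "weights") %||% rep(1, k)
    stopifnot(k >= 1, length(wts) == k, all(wts > 0), nz >= k)
    sizes <- pmax(1L, floor(nz * wts / sum(wts)))
    while (sum(sizes) > nz) sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
    sizes[k] <- sizes[k] + (nz - sum(sizes))
    frame_arch <- rep(seq_len(k), times = sizes)
    lps <- lapply(archetypes, function(a)
      utils::modifyList(config$lesion_params, a))
  } else {
    frame_arch <- rep(1L, nz)
    lps <- list(config$lesion_params)
  }
  # optional per-VOI lesion morphology randomisation: used when a dataset
  # should be heterogeneous across volumes (each VOI one morphology drawn at
  # random) rather than within them
  if (isTRUE(config$lesion_params$random_morphology) && calc) {
    rot <- runif(1, 0, 360)
    sc <- runif(4, c(0.6, 0.6, 0.7, 0.7), c(1.4, 1.6, 1.4, 1.4))
    lps <- lapply(lps, function(lp) {
      lp$arc_center_deg <- (lp$arc_center_deg + rot) %% 360
      lp$arc_extent_deg <- min(360, lp$arc_extent_deg * sc[1])
      lp$depth_px <- lp$depth_px * sc[2]
      lp$thickness_px <- lp$thickness_px * sc[3]
      # keep the scaled lesion inside the imaged depth
      reach <- config$lumen_radius_mean + config$lumen_radius_amplitude
      lp$thickness_px <- min(lp$thickness_px,
                             config$n_radial - reach - lp$depth_px - 2)
      lp
    })
  }
  drift <- config$lesion_params$z_drift
  arc_track <- smooth_track(nz, drift)            # radians
  # extent modulation amplitude scales with the drift rate (0.2 at the
  # default rate of 0.03, zero when drift is disabled)
  ext_amp <- min(0.2, drift * 20 / 3)
  ext_track <- 1 + ext_amp * sin(seq_len(nz) / nz * 2 * pi +
                                   runif(1, 0, 2 * pi))
  dep_track <- 1 + cumsum(rnorm(nz, 0, drift / 3))
  thk_track <- 1 + cumsum(rnorm(nz, 0, drift / 3))

  frames <- masks <- lumen <- guidewire <- vector("list", nz)
  for (z in seq_len(nz)) {
    lum <- lum_mean_track[z] +
      config$lumen_radius_amplitude * sin(theta - ph_track[z]) +
      2 * sin(3 * theta + ph_track[z])
    lum <- pmin(pmax(round(lum), 0L), nR - 1L)

    r <- matrix(seq_len(nR) - 1L, nR, nA)          # 0-based radius
    lum_m <- matrix(lum, nR, nA, byrow = TRUE)
    depth_from_lumen <- r - lum_m                  # <0 inside lumen

    base <- 0.85 * exp(-pmax(depth_from_lumen, 0) / 90)
    base[depth_from_lumen < 0] <- 0.015            # clear lumen

    mask <- matrix(0L, nR, nA)
    if (calc) {
      lp <- lps[[frame_arch[z]]]
      ctr <- lp$arc_center_deg * pi / 180 + arc_track[z]
      half <- lp$arc_extent_deg / 2 * pi / 180 * ext_track[z]
      half <- min(half, pi)
      dep <- pmax(0, lp$depth_px * dep_track[z])
      thk <- max(2, lp$thickness_px * thk_track[z])
      ang <- atan2(sin(theta - ctr), cos(theta - ctr))   # wrapped difference
      in_arc <- abs(ang) <= half
      arc_m <- matrix(in_arc, nR, nA, byrow = TRUE)
      lesion <- arc_m & depth_from_lumen >= dep &
        depth_from_lumen < dep + thk & r < nR
      base[lesion] <- base[lesion] * 0.15          # signal-poor, sharp border
      mask[lesion] <- 1L
    }

    # guidewire shadow: contiguous circular run of A-lines with no signal
    gw <- integer(0)
    if (config$guidewire_width > 0L) {
      gc_idx <- floor(gw_center[z] %% (2 * pi) / (2 * pi) * nA)
      gw <- (gc_idx + seq_len(config$guidewire_width) - 1L) %% nA  # 0-based
      base[, gw + 1L] <- 0.01
      mask[, gw + 1L] <- 0L
    }

    img <- base
    if (config$speckle_scale > 0) {
      spk <- matrix(rexp(nR * nA), nR, nA)
      img <- img * (1 - config$speckle_scale + config$speckle_scale * spk)
    }
    img <- pmin(pmax(img, 0), 1)

    frames[[z]] <- img
    masks[[z]] <- mask
    lumen[[z]] <- as.integer(lum)
    guidewire[[z]] <- as.integer(sort(gw))
  }
  structure(list(frames = frames, lumen = lumen, guidewire = guidewire,
                 masks = masks, voi_label = config$voi_label,
                 config = config),
            class = "polar_pullback")
}

#' @export
print.polar_pullback <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("<polar_pullback> %d frames of %d x %d (r x theta), label: %s\n",
              length(x$frames), d[1], d[2], x$voi_label))
  invisible(x)
}

#' Generate a synthetic multi-VOI dataset
#'
#' Draws independent volumes of interest, each with its own seed derived from
#' the master seed, mixing normal (lesion-free) and calcification volumes.
#' VOI lengths are drawn log-uniformly from `n_frames_range`, reproducing a
#' clinical distribution of lesion sizes (many short, few long volumes).
#'
#' @param n_vois_normal,n_vois_calc Number of normal / calcification VOIs.
#' @param group_structure Optional list of lesion-morphology archetypes
#'   (passed to [generate_voi()] for every calcification VOI).
#' @param seed Master seed.
#' @param n_frames_range Integer range of frames per VOI.
#' @param config Template [phantom_config()]; per-VOI seed, label and length
#'   are filled in.
#' @return List of `polar_pullback` objects, normal VOIs first.
#' @export
generate_dataset <- function(n_vois_normal, n_vois_calc,
                             group_structure = NULL, seed = 1L,
                             n_frames_range = c(10L, 200L),
                             config = phantom_config()) {
  stopifnot(n_vois_normal >= 0, n_vois_calc >= 0)
  n <- n_vois_normal + n_vois_calc
  if (n == 0L) return(list())
  meta <- with_seed(seed, list(
    seeds = sample.int(.Machine$integer.max - 1L, n),
    sizes = round(exp(runif(n, log(n_frames_range[1]), log(n_frames_range[2]))))
  ))
  labels <- c(rep("normal", n_vois_normal), rep("calcification", n_vois_calc))
  lapply(seq_len(n), function(i) {
    cfg <- config
    cfg$voi_label <- labels[i]
    cfg$n_frames <- as.integer(meta$sizes[i])
    cfg$seed <- meta$seeds[i]
    generate_voi(cfg, archetypes = if (labels[i] == "calcification")
      group_structure else NULL)
  })
}
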