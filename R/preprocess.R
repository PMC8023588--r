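#' Preprocessing configuration
#'
#' Parameters of the polar-domain preprocessing chain: guidewire zeroing,
#' lumen pixel-shift alignment, radial cropping to the tissue band, log
#' transform and Gaussian speckle reduction.
#'
#' @param crop_depth Radial pixels kept from the lumen boundary (about 1 mm
#'   of tissue at a typical 5 um pixel pitch).
#' @param gauss_kernel Odd `(h, w)` dimensions of the Gaussian kernel.
#' @param gauss_sigma Kernel standard deviation, in pixels.
#' @param log_epsilon Offset added before the log transform so zeroed pixels
#'   stay finite.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(crop_depth = 200L, gauss_kernel = c(7L, 7L),
                              gauss_sigma = 1, log_epsilon = 1e-6) {
  stopifnot(crop_depth >= 1, length(gauss_kernel) == 2,
            all(gauss_kernel %% 2 == 1), gauss_sigma > 0, log_epsilon > 0)
  structure(list(crop_depth = as.integer(crop_depth),
                 gauss_kernel = as.integer(gauss_kernel),
                 gauss_sigma = gauss_sigma, log_epsilon = log_epsilon),
            class = "preprocess_config")
}

gaussian_kernel <- function(dims, sigma) {
  ki <- seq_len(dims[1]) - (dims[1] + 1) / 2
  kj <- seq_len(dims[2]) - (dims[2] + 1) / 2
  k <- exp(-outer(ki^2, kj^2, "+") / (2 * sigma^2))
  k / sum(k)
}

#' Detect guidewire-shadow A-lines
#'
#' The metal guidewire blocks the beam, leaving a contiguous (circularly
#' wrapping) run of A-lines with essentially no tissue signal. The detector
#' sums each A-line's intensity beyond the lumen boundary and flags the
#' longest circular run whose sum falls below an adaptive threshold
#' (median - `c_mad` * MAD of the per-A-line sums).
#'
#' @param frame `n_radial x n_alines` matrix, intensities in `[0, 1]`.
#' @param lumen Optional 0-based lumen trace; when given, only pixels at or
#'   beyond the lumen contribute to the per-A-line sums.
#' @param c_mad Threshold multiplier.
#' @param min_width Minimum run width (A-lines) to report a shadow.
#' @return 0-based A-line indices (possibly empty), sorted.
#' @export
detect_guidewire_alines <- function(frame, lumen = NULL, c_mad = 3,
                                    min_width = 3L) {
  nA <- ncol(frame)
  if (is.null(lumen)) {
    sums <- colSums(frame)
  } else {
    stopifnot(length(lumen) == nA)
    sums <- vapply(seq_len(nA), function(j) {
      r0 <- min(lumen[j] + 1L, nrow(frame))
      sum(frame[r0:nrow(frame), j])
    }, numeric(1))
  }
  thr <- median(sums) - c_mad * mad(sums)
  low <- sums < thr
  if (!any(low)) return(integer(0))
  if (all(low)) return(seq_len(nA) - 1L)
  # longest circular run of TRUE: rotate so position 1 is FALSE, then rle
  start <- which(!low)[1L]
  rot <- low[((seq_len(nA) - 1L + start - 1L) %% nA) + 1L]
  r <- rle(rot)
  ends <- cumsum(r$lengths)
  runs <- which(r$values)
  if (length(runs) == 0L) return(integer(0))
  best <- runs[which.max(r$lengths[runs])]
  if (r$lengths[best] < min_width) return(integer(0))
  pos <- (ends[best] - r$lengths[best] + 1L):ends[best]      # in rotated frame
  orig <- ((pos - 1L + start - 1L) %% nA)                    # 0-based
  sort(orig)
}

#' Zero out guidewire A-lines
#'
#' Sets the listed A-lines to zero in the image (and, when given, the mask),
#' since shadowed A-lines carry no tissue information. All other A-lines are
#' untouched; the operation is idempotent.
#'
#' @param frame `n_radial x n_alines` image matrix.
#' @param alines 0-based A-line indices.
#' @param mask Optional binary mask treated identically.
#' @return The frame, or `list(frame, mask)` when a mask is supplied.
#' @export
zero_guidewire <- function(frame, alines, mask = NULL) {
  if (length(alines)) {
    stopifnot(all(alines >= 0), all(alines < ncol(frame)))
    frame[, alines + 1L] <- 0
    if (!is.null(mask)) mask[, alines + 1L] <- 0L
  }
  if (is.null(mask)) frame else list(frame = frame, mask = mask)
}

#' Align tissue by per-A-line radial pixel shifting
#'
#' Translates each A-line radially by its lumen offset so that row 1 of the
#' result corresponds to the lumen boundary in every A-line, correcting for
#' eccentric lumen and catheter position. Shifts are integer (masks stay
#' binary); vacated deep pixels are zero-filled. The same shift is applied to
#' the mask. The applied shifts are recorded so the operation is invertible
#' within the retained depth.
#'
#' @param frame,mask `n_radial x n_alines` matrices.
#' @param lumen_trace 0-based radial offset of the first tissue pixel per
#'   A-line; length must equal `ncol(frame)`.
#' @return An `aligned_frame` list: `image`, `mask`,
#'   `provenance = list(shifts, guidewire)`.
#' @export
pixel_shift_align <- function(frame, mask, lumen_trace) {
  nR <- nrow(frame); nA <- ncol(frame)
  if (length(lumen_trace) != nA)
    stop("lumen trace length ", length(lumen_trace),
         " does not match n_alines ", nA)
  stopifnot(all(lumen_trace >= 0), all(lumen_trace < nR))
  img <- matrix(0, nR, nA)
  msk <- matrix(0L, nR, nA)
  for (j in seq_len(nA)) {
    s <- lumen_trace[j]
    if (s == 0L) {
      img[, j] <- frame[, j]
      msk[, j] <- mask[, j]
    } else {
      keep <- (s + 1L):nR
      img[seq_along(keep), j] <- frame[keep, j]
      msk[seq_along(keep), j] <- mask[keep, j]
    }
  }
  structure(list(image = img, mask = msk,
                 provenance = list(shifts = as.integer(lumen_trace),
                                   guidewire = integer(0))),
            class = "aligned_frame")
}

#' Crop, log-transform and smooth an aligned frame
#'
#' Keeps the first `crop_depth` rows (the tissue band below the lumen), maps
#' intensities through `log(x + log_epsilon)`, rescales each frame min-max to
#' `[0, 1]`, and applies Gaussian filtering (replicate-padded). The mask is
#' cropped identically but never filtered, and guidewire A-lines recorded in
#' the provenance are re-zeroed after filtering so they stay exactly zero.
#'
#' @param aligned An `aligned_frame` from [pixel_shift_align()].
#' @param cfg A [preprocess_config()].
#' @return An `aligned_frame` with cropped, denoised image.
#' @export
crop_log_smooth <- function(aligned, cfg = preprocess_config()) {
  stopifnot(inherits(aligned, "aligned_frame"))
  img <- aligned$image
  if (cfg$crop_depth > nrow(img))
    stop("crop_depth ", cfg$crop_depth, " exceeds frame depth ", nrow(img))
  rows <- seq_len(cfg$crop_depth)
  img <- img[rows, , drop = FALSE]
  msk <- aligned$mask[rows, , drop = FALSE]
  img <- log(img + cfg$log_epsilon)
  rng <- range(img)
  img <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1]) else img * 0
  kern <- gaussian_kernel(cfg$gauss_kernel, cfg$gauss_sigma)
  img <- cpp_filter2_replicate(img, kern)
  gw <- aligned$provenance$guidewire
  if (length(gw)) img[, gw + 1L] <- 0
  structure(list(image = img, mask = msk, provenance = aligned$provenance),
            class = "aligned_frame")
}

#' Preprocess every frame of a pullback
#'
#' Applies the full chain per frame: guidewire detection (or the pullback's
#' own annotation), zeroing, lumen pixel-shift alignment, crop, log transform
#' and Gaussian smoothing, preserving frame order.
#'
#' @param pullback A `polar_pullback`.
#' @param cfg A [preprocess_config()].
#' @param guidewire `"annotation"` uses the pullback's stored guidewire
#'   indices (when present); `"detect"` runs [detect_guidewire_alines()].
#' @return List of `aligned_frame` objects, one per frame.
#' @export
preprocess_voi <- function(pullback, cfg = preprocess_config(),
                           guidewire = c("annotation", "detect")) {
  stopifnot(inherits(pullback, "polar_pullback"))
  guidewire <- match.arg(guidewire)
  n <- length(pullback$frames)
  out <- vector("list", n)
  for (z in seq_len(n)) {
    res <- tryCatch({
      frame <- pullback$frames[[z]]
      lum <- pullback$lumen[[z]]
      gw <- if (guidewire == "annotation" &&
                !is.null(pullback$guidewire[[z]]))
        pullback$guidewire[[z]]
      else detect_guidewire_alines(frame, lumen = lum)
      zg <- zero_guidewire(frame, gw, pullback$masks[[z]])
      al <- pixel_shift_align(zg$frame, zg$mask, lum)
      al$provenance$guidewire <- as.integer(gw)
      al$provenance$frame_id <- z - 1L
      crop_log_smooth(al, cfg)
    }, error = function(e)
      stop("frame ", z - 1L, ": ", conditionMessage(e), call. = FALSE))
    out[[z]] <- res
  }
  out
}
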