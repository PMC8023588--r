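# On-disk interchange: multi-page TIFF for frame and mask stacks, CSV for
# lumen traces (frame, a-line, offset; all 0-based), JSON for VOI metadata
# and sampling plans.

#' Write a pullback to a directory
#'
#' Writes `frames.tif` and `masks.tif` (multi-page, one page per frame),
#' `lumen.csv` (columns `frame`, `aline`, `offset`, 0-based) and
#' `meta.json` (label, frame count, guidewire indices, config echo).
#'
#' @param pullback A `polar_pullback`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pullback <- function(pullback, dir) {
  stopifnot(inherits(pullback, "polar_pullback"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(pullback$frames, file.path(dir, "frames.tif"),
                  bits.per.sample = 16L)
  tiff::writeTIFF(lapply(pullback$masks, function(m) m * 1),
                  file.path(dir, "masks.tif"), bits.per.sample = 8L)
  lum <- do.call(rbind, lapply(seq_along(pullback$lumen), function(z)
    data.frame(frame = z - 1L,
               aline = seq_along(pullback$lumen[[z]]) - 1L,
               offset = pullback$lumen[[z]])))
  write.csv(lum, file.path(dir, "lumen.csv"), row.names = FALSE)
  meta <- list(voi_label = pullback$voi_label,
               n_frames = length(pullback$frames),
               guidewire = pullback$guidewire,
               config = pullback$config[setdiff(names(pullback$config),
                                                "lesion_params")],
               lesion_params = pullback$config$lesion_params)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a pullback written by [write_pullback()]
#'
#' @param dir Directory containing `frames.tif`, `masks.tif`, `lumen.csv`,
#'   `meta.json`.
#' @return A `polar_pullback`.
#' @export
read_pullback <- function(dir) {
  frames <- tiff::readTIFF(file.path(dir, "frames.tif"), all = TRUE)
  masks <- lapply(tiff::readTIFF(file.path(dir, "masks.tif"), all = TRUE),
                  function(m) {
                    out <- matrix(0L, nrow(m), ncol(m))
                    out[m > 0.5] <- 1L
                    out
                  })
  lum <- utils::read.csv(file.path(dir, "lumen.csv"))
  lumen <- lapply(split(lum$offset, lum$frame), as.integer)
  names(lumen) <- NULL
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  # read per-frame guidewire index lists without simplification: equal-length
  # vectors would otherwise collapse into a matrix
  gw_raw <- jsonlite::read_json(file.path(dir, "meta.json"))$guidewire
  gw <- lapply(seq_along(frames), function(z) {
    g <- if (z <= length(gw_raw)) unlist(gw_raw[[z]]) else integer(0)
    as.integer(g %||% integer(0))
  })
  structure(list(frames = frames, lumen = lumen, guidewire = gw,
                 masks = masks, voi_label = meta$voi_label,
                 config = meta$config),
            class = "polar_pullback")
}

#' Serialize a sampling plan to JSON
#'
#' @param plan A `sampling_plan`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "sampling_plan"))
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a sampling plan written by [write_plan()]
#'
#' @param path JSON file.
#' @return A `sampling_plan`.
#' @export
read_plan <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_sampling_plan(p$voi_id %||% NA, p$method, p$ratio, p$selected,
                    p$seed %||% NA_integer_, p$details %||% list())
}

#' Write preprocessed frames and provenance
#'
#' Writes the aligned, cropped images as a multi-page TIFF plus a JSON
#' provenance record of per-frame shifts and guidewire indices.
#'
#' @param aligned_frames List of `aligned_frame` objects.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_preprocessed <- function(aligned_frames, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  imgs <- lapply(aligned_frames, function(f) pmin(pmax(f$image, 0), 1))
  tiff::writeTIFF(imgs, file.path(dir, "preprocessed.tif"),
                  bits.per.sample = 16L)
  tiff::writeTIFF(lapply(aligned_frames, function(f) f$mask * 1),
                  file.path(dir, "masks.tif"), bits.per.sample = 8L)
  prov <- lapply(aligned_frames, `[[`, "provenance")
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a metrics report to JSON
#'
#' The PR curve is written alongside as CSV when `pr_csv` is given.
#'
#' @param report A `metrics_report`.
#' @param path Output JSON file.
#' @param pr_csv Optional CSV path for the PR curve points.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path, pr_csv = NULL) {
  stopifnot(inherits(report, "metrics_report"))
  out <- unclass(report)
  out$pr_curve <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(pr_csv))
    write.csv(report$pr_curve, pr_csv, row.names = FALSE)
  invisible(path)
}
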