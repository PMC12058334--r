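# Laser speckle contrast analysis (LASCA) baseline.  Spatial contrast
# K = sigma / mu over non-overlapping windows; a single reference video
# of known velocity fixes the proportionality constant A = V * K^2, and
# test videos are read out as V_hat = A / K^2.

#' Local speckle contrast of one frame
#'
#' Partitions the frame into non-overlapping `window` x `window` tiles
#' and computes `K = sd / mean` (population standard deviation) of the
#' intensities in each tile; trailing pixels that do not fill a tile are
#' ignored.  Tiles with zero mean are excluded.
#'
#' @param frame Numeric matrix of intensities.
#' @param window Tile side in pixels, odd and >= 3.
#' @return A `contrast_result`: list with `contrast_map` (matrix of
#'   per-tile K, `NA` for excluded tiles), `mean_contrast` and `window`.
#' @export
local_contrast <- function(frame, window = 7L) {
  if (window < 3L || window %% 2L == 0L)
    stopf("window must be odd and >= 3, got %d", window)
  if (nrow(frame) < window || ncol(frame) < window)
    stopf("frame (%dx%d) is smaller than the %d-pixel window",
          nrow(frame), ncol(frame), window)
  nh <- nrow(frame) %/% window
  nw <- ncol(frame) %/% window
  kmap <- matrix(NA_real_, nh, nw)
  for (i in seq_len(nh)) {
    for (j in seq_len(nw)) {
      tile <- frame[((i - 1) * window + 1):(i * window),
                    ((j - 1) * window + 1):(j * window)]
      mu <- mean(tile)
      if (mu == 0) next
      kmap[i, j] <- sqrt(mean((tile - mu)^2)) / mu
    }
  }
  if (all(is.na(kmap)))
    stopf("no window with nonzero mean intensity: cannot compute contrast")
  structure(list(contrast_map = kmap,
                 mean_contrast = mean(kmap, na.rm = TRUE),
                 window = as.integer(window)),
            class = "contrast_result")
}

#' Mean speckle contrast of a video
#'
#' Average of the per-frame mean local contrast over all frames.  With
#' exposure integration, faster flow blurs the speckle within each
#' exposure and lowers this value -- the mechanism LASCA exploits.
#'
#' @param video A `speckle_video` or a T x H x W array.
#' @param window Tile side, see [local_contrast()].
#' @return Scalar mean contrast K-bar.
#' @export
video_mean_contrast <- function(video, window = 7L) {
  frames <- if (inherits(video, "speckle_video")) video$frames else video
  n <- dim(frames)[1]
  if (is.na(n) || n < 1L) stopf("video has no frames")
  mean(vapply(seq_len(n), function(t)
    local_contrast(frames[t, , ], window)$mean_contrast, numeric(1)))
}

#' Single-point LASCA calibration
#'
#' Fixes the proportionality constant of the `V ~ 1/K^2` readout from
#' one reference video of known velocity: `A = V_ref * K_ref^2`.
#'
#' @param ref_video Reference `speckle_video` (or array).
#' @param known_velocity Its true velocity, cm/s (> 0).
#' @param window Contrast window, see [local_contrast()].
#' @param ref_depth Depth at which the reference was recorded (mm),
#'   recorded for provenance.
#' @return A `lasca_calibration`: list with `constant_A`, `ref_velocity`,
#'   `ref_contrast`, `ref_depth`, `window`.
#' @export
calibrate_single_point <- function(ref_video, known_velocity,
                                   window = 7L, ref_depth = NA_real_) {
  check_number(known_velocity, "known_velocity", lower = 0,
               strict_lower = TRUE)
  k <- video_mean_contrast(ref_video, window)
  structure(list(constant_A = known_velocity * k^2,
                 ref_velocity = known_velocity, ref_contrast = k,
                 ref_depth = ref_depth, window = as.integer(window)),
            class = "lasca_calibration")
}

#' @export
print.lasca_calibration <- function(x, ...) {
  cat(sprintf(
    "lasca_calibration: A = %.4g (V_ref %.3g cm/s, K_ref %.4g, depth %s mm)\n",
    x$constant_A, x$ref_velocity, x$ref_contrast,
    if (is.na(x$ref_depth)) "?" else format(x$ref_depth)))
  invisible(x)
}

#' LASCA velocity estimate
#'
#' `V_hat = A / K^2` with the calibration's window.
#'
#' @param calibration A [calibrate_single_point()] result.
#' @param video Test `speckle_video` (or array).
#' @return Estimated velocity, cm/s.
#' @export
estimate_velocity <- function(calibration, video) {
  k <- video_mean_contrast(video, calibration$window)
  if (k == 0)
    stopf("video has zero speckle contrast: velocity estimate diverges")
  calibration$constant_A / k^2
}

#' Cross-depth LASCA calibration-transfer experiment
#'
#' Calibrates on one video recorded at `calibration_depth` and applies
#' that single calibration to test videos at each requested depth,
#' reporting per-video relative errors.  Applying a calibration at a
#' depth other than its own breaks the `V ~ 1/K^2` readout because the
#' depth-dependent static scattering and blur shift the contrast scale.
#' The reference video is the one at `calibration_depth` whose velocity
#' is closest to the median nonzero velocity there (i.e. a medium-flow
#' reference).
#'
#' @param dataset A `phantom_dataset` with videos in memory.
#' @param calibration_depth Depth (mm) whose videos calibrate A.
#' @param test_depths Depths (mm) to evaluate; each must be present in
#'   the dataset.
#' @param window Contrast window.
#' @return A `cross_depth_result`: list with `table` (data frame:
#'   depth_mm, video_id, true_velocity, estimated_velocity, rel_error),
#'   `summary` (per-depth mean signed and absolute relative error) and
#'   `calibration`.
#' @export
cross_depth_experiment <- function(dataset, calibration_depth,
                                   test_depths, window = 7L) {
  man <- dataset$manifest
  for (d in unique(c(calibration_depth, test_depths)))
    if (!any(man$depth_mm == d))
      stopf("dataset has no videos at depth %g mm", d)
  cal_rows <- man[man$depth_mm == calibration_depth &
                    man$velocity_cm_s > 0, , drop = FALSE]
  if (nrow(cal_rows) == 0L)
    stopf("no nonzero-velocity video at calibration depth %g mm",
          calibration_depth)
  med <- stats::median(cal_rows$velocity_cm_s)
  ref_row <- cal_rows[which.min(abs(cal_rows$velocity_cm_s - med)), ]
  calibration <- calibrate_single_point(
    dataset$videos[[ref_row$video_id]], ref_row$velocity_cm_s,
    window = window, ref_depth = calibration_depth)

  rows <- list()
  for (d in test_depths) {
    test_rows <- man[man$depth_mm == d & man$velocity_cm_s > 0 &
                       man$video_id != ref_row$video_id, , drop = FALSE]
    for (i in seq_len(nrow(test_rows))) {
      r <- test_rows[i, ]
      vhat <- estimate_velocity(calibration, dataset$videos[[r$video_id]])
      rows[[length(rows) + 1L]] <- data.frame(
        depth_mm = d, video_id = r$video_id,
        true_velocity = r$velocity_cm_s, estimated_velocity = vhat,
        rel_error = (vhat - r$velocity_cm_s) / r$velocity_cm_s,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  summary <- do.call(rbind, lapply(split(tab, tab$depth_mm), function(s)
    data.frame(depth_mm = s$depth_mm[1], n = nrow(s),
               mean_rel_error = mean(s$rel_error),
               mean_abs_rel_error = mean(abs(s$rel_error)))))
  rownames(summary) <- NULL
  structure(list(table = tab, summary = summary,
                 calibration = calibration),
            class = "cross_depth_result")
}

#' @export
print.cross_depth_result <- function(x, ...) {
  print(x$calibration)
  print(x$summary, row.names = FALSE)
  invisible(x)
}
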