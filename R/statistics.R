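# Summary statistics of speckle dynamics used to validate the simulator
# and to characterise recordings.

#' Full-frame speckle contrast
#'
#' `sd / mean` of the intensities of one frame (population standard
#' deviation).  Fully developed polarized speckle has contrast 1.
#'
#' @param frame Numeric matrix (or the intensity `|A|^2` of a field).
#' @return Scalar contrast.
#' @export
frame_contrast <- function(frame) {
  mu <- mean(frame)
  if (mu == 0) stopf("frame has zero mean intensity")
  sqrt(mean((frame - mu)^2)) / mu
}

#' Lag-1 temporal autocorrelation of pixel intensity
#'
#' Each pixel's temporal mean is removed before correlating consecutive
#' frames (the standard temporal-correlation estimator for dynamic
#' speckle); this isolates the fluctuating part of the signal from the
#' static speckle background, which otherwise dominates the statistic
#' for deep vessels.  Faster flow decorrelates the field more between
#' frames and lowers this value.
#'
#' @param video A `speckle_video` or T x H x W array (T >= 2).
#' @return Correlation in `[-1, 1]`.
#' @export
lag1_autocorr <- function(video) {
  frames <- if (inherits(video, "speckle_video")) video$frames else video
  n <- dim(frames)[1]
  if (is.na(n) || n < 2L) stopf("need at least 2 frames")
  m <- matrix(as.numeric(frames), nrow = n)
  m <- sweep(m, 2, colMeans(m))
  sum(m[-n, ] * m[-1, ]) / sqrt(sum(m[-n, ]^2) * sum(m[-1, ]^2))
}
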