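# Complex speckle-field machinery.  A fully developed speckle field is
# synthesised as a circular complex Gaussian random field band-limited by
# a circular pupil in the Fourier domain: white complex Gaussian noise is
# masked by a pupil of radius `grain_radius` (in Nyquist units) and
# inverse-transformed.  This reproduces the statistics of free-space
# propagation from a rough surface -- negative-exponential intensity,
# unit contrast -- with the pupil radius setting the speckle grain size
# (smaller pupil, larger grains), without numerical diffraction
# integrals.

fft_freq <- function(n) {
  i <- 0:(n - 1L)
  ifelse(i <= n / 2, i, i - n) / n          # cycles per pixel
}

pupil_mask <- function(height, width, grain_radius) {
  fy <- fft_freq(height) * 2                # Nyquist units: Nyquist = 1
  fx <- fft_freq(width) * 2
  outer(fy^2, fx^2, "+") <= grain_radius^2
}

# fresh unit-mean-intensity field; consumes the current RNG state
field_noise <- function(height, width, mask) {
  z <- matrix(stats::rnorm(height * width), height, width) +
    1i * matrix(stats::rnorm(height * width), height, width)
  a <- stats::fft(z * mask, inverse = TRUE) / sqrt(height * width)
  a / sqrt(mean(Mod(a)^2))
}

new_speckle_field <- function(amplitude, grain_radius) {
  structure(list(amplitude = amplitude, grain_radius = grain_radius),
            class = "speckle_field")
}

#' Generate a fully developed speckle field
#'
#' Draws one realisation of a band-limited circular complex Gaussian
#' field.  Its intensity `|A|^2` follows a negative-exponential law with
#' mean normalised to 1, so the spatial contrast (sd/mean) of a single
#' frame is 1 -- the signature of fully developed, polarised speckle.
#'
#' @param params A [simulation_params()] object (only `height`, `width`
#'   and `grain_radius` are used).
#' @return A `speckle_field`: list with complex `amplitude` (height x
#'   width) and `grain_radius`.
#' @export
generate_field <- function(params) {
  check_number(params$grain_radius, "grain_radius", lower = 0, upper = 1,
               strict_lower = TRUE)
  mask <- pupil_mask(params$height, params$width, params$grain_radius)
  new_speckle_field(field_noise(params$height, params$width, mask),
                    params$grain_radius)
}

#' Evolve a speckle field by one correlation step
#'
#' First-order autoregressive update of the complex field,
#' `A' = rho * A + sqrt(1 - rho^2) * eps`, where `eps` is an independent
#' field with the same pupil and marginal statistics.  The update leaves
#' the single-frame statistics invariant while the field decorrelates at
#' rate set by `rho` (see [decorrelation_factor()]).
#'
#' @param field A `speckle_field`.
#' @param rho Surviving correlation in `[0, 1]`; 1 freezes the field.
#' @return The evolved `speckle_field`.
#' @export
evolve_field <- function(field, rho) {
  check_number(rho, "rho", lower = 0, upper = 1)
  if (rho == 1) return(field)
  h <- nrow(field$amplitude)
  w <- ncol(field$amplitude)
  mask <- pupil_mask(h, w, field$grain_radius)
  eps <- field_noise(h, w, mask)
  new_speckle_field(rho * field$amplitude + sqrt(1 - rho^2) * eps,
                    field$grain_radius)
}

# Gaussian blur (sd `sigma` px) and horizontal subpixel shift `dx` px,
# applied in one Fourier-domain pass (exact under the periodic field
# model; the speckle field itself is synthesised on the same torus).
blur_shift <- function(img, sigma, dx) {
  if (sigma == 0 && dx == 0) return(img)
  h <- nrow(img)
  w <- ncol(img)
  fy <- fft_freq(h)
  fx <- fft_freq(w)
  transfer <- exp(-2 * pi^2 * sigma^2 * outer(fy^2, fx^2, "+"))
  if (dx != 0)
    transfer <- transfer *
      matrix(exp(-2i * pi * fx * dx), h, w, byrow = TRUE)
  Re(stats::fft(stats::fft(img) * transfer, inverse = TRUE)) / (h * w)
}
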