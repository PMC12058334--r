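#' Depth-dependent degradation profile
#'
#' Maps vessel depth to the fraction of statically scattered light and
#' the imaging blur it causes.  Deeper vessels contribute less moving
#' scatter relative to the overlying static tissue (larger
#' `static_fraction`) and suffer stronger diffusive blur, which is what
#' progressively washes out speckle contrast with depth.
#'
#' @param depth_mm Vessel-top depth below the surface, one of 0, 5, 10.
#' @return List with `static_fraction` and `blur_sigma` (pixels).
#' @export
depth_profile <- function(depth_mm) {
  i <- match(depth_mm, c(0, 5, 10))
  if (is.na(i)) stopf("depth must be 0, 5 or 10 mm, got %g", depth_mm)
  list(static_fraction = c(0.2, 0.5, 0.7)[i], blur_sigma = c(0, 1, 2)[i])
}

#' Parameters of one simulated phantom recording
#'
#' Full generative description of a single defocused dynamic-speckle
#' video.  The `"desk"` profile (64 x 64 px, 5 s) keeps simulation fast;
#' the `"full"` profile reproduces the acquisition geometry of the
#' phantom recordings (224 x 224 px, 300 frames/s, 33 s, i.e. 9900
#' frames).  `static_fraction` and `blur_sigma` default to the
#' [depth_profile()] of `depth`.
#'
#' @param velocity Cycle-mean flow velocity, cm/s (>= 0).
#' @param depth Vessel-top depth below the surface, mm (0, 5 or 10).
#' @param diameter Vessel inner diameter, mm (3 or 6).
#' @param profile `"desk"` or `"full"` size profile.
#' @param height,width Frame size in pixels.
#' @param fps Frame rate, frames/s.
#' @param duration Recording length, s (`fps * duration` must be an
#'   integer frame count).
#' @param wavelength Optical wavelength, m (532 nm green laser).
#' @param propagation_distance Object-to-camera distance, m.
#' @param grain_radius Pupil radius in Nyquist units, in (0, 1];
#'   controls speckle grain size (smaller value, coarser grains).
#' @param pulse_freq Pulse-emulator frequency, Hz.
#' @param pulse_modulation Raised-sine modulation depth m in [0, 1).
#' @param static_fraction Fraction beta of statically scattered
#'   intensity, in [0, 1).
#' @param blur_sigma Gaussian blur sd, pixels (>= 0).
#' @param decorrelation_scale Velocity-to-correlation-time scale k_v, cm;
#'   the field correlation time is `k_v / velocity`.
#' @param exposure_substeps Field sub-steps S averaged within one frame
#'   exposure (integer >= 1, 100% duty cycle).
#' @param translation_amplitude Amplitude of the pulse-driven global
#'   pattern translation, pixels.
#' @param noise_sigma Additive sensor noise sd, gray levels.
#' @param gain Gray level assigned to unit (mean) intensity before
#'   clipping to [0, 255].
#' @param seed Integer RNG seed for this video.
#' @return A `simulation_params` object (a validated list).
#' @export
simulation_params <- function(velocity = 0,
                              depth = 0,
                              diameter = 3,
                              profile = c("desk", "full"),
                              height = NULL,
                              width = NULL,
                              fps = 300,
                              duration = NULL,
                              wavelength = 532e-9,
                              propagation_distance = 0.5,
                              grain_radius = 0.4,
                              pulse_freq = 1,
                              pulse_modulation = 0.3,
                              static_fraction = NULL,
                              blur_sigma = NULL,
                              decorrelation_scale = 5.5 * 10 / 300,
                              exposure_substeps = 4,
                              translation_amplitude = 1.0,
                              noise_sigma = 0.6,
                              gain = 40,
                              seed = 1L) {
  profile <- match.arg(profile)
  if (is.null(height)) height <- if (profile == "desk") 64L else 224L
  if (is.null(width)) width <- if (profile == "desk") 64L else 224L
  if (is.null(duration)) duration <- if (profile == "desk") 5 else 33
  prof <- depth_profile(depth)
  if (is.null(static_fraction)) static_fraction <- prof$static_fraction
  if (is.null(blur_sigma)) blur_sigma <- prof$blur_sigma

  check_number(velocity, "velocity", lower = 0)
  if (!diameter %in% c(3, 6))
    stopf("diameter must be 3 or 6 mm, got %g", diameter)
  check_number(fps, "fps", lower = 0, strict_lower = TRUE)
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  n_frames <- fps * duration
  if (abs(n_frames - round(n_frames)) > 1e-6)
    stopf("fps * duration = %g is not an integer frame count", n_frames)
  check_number(grain_radius, "grain_radius", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_number(pulse_modulation, "pulse_modulation", lower = 0)
  if (pulse_modulation >= 1)
    stopf("pulse_modulation must be < 1, got %g", pulse_modulation)
  check_number(static_fraction, "static_fraction", lower = 0)
  if (static_fraction >= 1)
    stopf("static_fraction must be < 1, got %g", static_fraction)
  check_number(blur_sigma, "blur_sigma", lower = 0)
  check_number(decorrelation_scale, "decorrelation_scale",
               lower = 0, strict_lower = TRUE)
  if (exposure_substeps < 1 || exposure_substeps != round(exposure_substeps))
    stopf("exposure_substeps must be a positive integer, got %g",
          exposure_substeps)
  check_number(translation_amplitude, "translation_amplitude", lower = 0)
  check_number(noise_sigma, "noise_sigma", lower = 0)
  check_number(gain, "gain", lower = 0, strict_lower = TRUE)

  structure(list(
    height = as.integer(height), width = as.integer(width),
    fps = fps, duration = duration,
    wavelength = wavelength, propagation_distance = propagation_distance,
    grain_radius = grain_radius,
    velocity = velocity, depth = depth, diameter = diameter,
    pulse_freq = pulse_freq, pulse_modulation = pulse_modulation,
    static_fraction = static_fraction, blur_sigma = blur_sigma,
    decorrelation_scale = decorrelation_scale,
    exposure_substeps = as.integer(exposure_substeps),
    translation_amplitude = translation_amplitude,
    noise_sigma = noise_sigma, gain = gain,
    seed = as.integer(seed), bit_depth = 8L
  ), class = "simulation_params")
}

#' @export
print.simulation_params <- function(x, ...) {
  cat(sprintf(
    "simulation_params: %dx%d px, %g fps, %g s (%d frames)\n",
    x$height, x$width, x$fps, x$duration, round(x$fps * x$duration)))
  cat(sprintf(
    "  vessel %g mm at %g mm depth, v = %g cm/s (beta %.2f, blur %g px)\n",
    x$diameter, x$depth, x$velocity, x$static_fraction, x$blur_sigma))
  invisible(x)
}

#' Render one 8-bit camera frame
#'
#' Exposure-integrates the dynamic speckle intensity over the substep
#' fields, mixes in the static tissue speckle, applies depth blur, the
#' pulse-driven global translation, additive sensor noise, and quantizes
#' to 8 bits with a fixed gain:
#' `I = (1 - beta) * mean_s |A_s|^2 + beta * |A_static|^2`.
#'
#' @param substep_fields List of `speckle_field`s, the S intra-exposure
#'   evolutions of the dynamic field.
#' @param static_field The frozen tissue `speckle_field`.
#' @param params [simulation_params()].
#' @param displacement Horizontal subpixel translation (pixels).
#' @return Integer matrix (height x width) of gray values in [0, 255].
#' @export
render_frame <- function(substep_fields, static_field, params,
                         displacement = 0) {
  if (length(substep_fields) == 0L)
    stopf("at least one exposure substep field is required")
  i_dyn <- Reduce(`+`, lapply(substep_fields,
                              function(f) Mod(f$amplitude)^2)) /
    length(substep_fields)
  render_intensity(i_dyn, Mod(static_field$amplitude)^2, params,
                   displacement)
}

# intensity-domain half of render_frame, shared with simulate_video
render_intensity <- function(i_dyn, i_stat, params, displacement) {
  beta <- params$static_fraction
  img <- (1 - beta) * i_dyn + beta * i_stat
  img <- blur_shift(img, params$blur_sigma, displacement)
  img <- img * params$gain
  if (params$noise_sigma > 0)
    img <- img + stats::rnorm(length(img), 0, params$noise_sigma)
  frame <- matrix(as.integer(pmin(255, pmax(0, round(img)))),
                  nrow(img), ncol(img))
  frame
}

#' Simulate one dynamic speckle video
#'
#' Runs the generative chain frame by frame: the instantaneous pulsatile
#' velocity sets the per-substep decorrelation factor, the complex field
#' is evolved through S substeps per exposure, and each frame is
#' rendered, degraded and quantized.  Zero-velocity recordings keep the
#' field frozen (`rho = 1`) so only sensor noise and the residual
#' pulse-emulator translation move the pattern.  Fully deterministic
#' given `params$seed`.
#'
#' @param params [simulation_params()].
#' @param condition Optional flow-condition label stored with the video.
#' @param video_id Optional identifier string.
#' @return A `speckle_video`: list with integer `frames` (T x H x W),
#'   `fps`, `params`, `condition`, `video_id`.
#' @export
simulate_video <- function(params, condition = NA_character_,
                           video_id = "video") {
  stopifnot(inherits(params, "simulation_params"))
  with_seed(params$seed, {
    h <- params$height
    w <- params$width
    n_frames <- as.integer(round(params$fps * params$duration))
    s <- params$exposure_substeps
    mask <- pupil_mask(h, w, params$grain_radius)
    i_stat <- Mod(field_noise(h, w, mask))^2
    amp <- field_noise(h, w, mask)
    zero_flow <- params$velocity == 0
    dt_sub <- 1 / (params$fps * s)
    frames <- array(0L, dim = c(n_frames, h, w))
    i_dyn_frozen <- if (zero_flow) Mod(amp)^2
    for (t in seq_len(n_frames)) {
      if (zero_flow) {
        i_dyn <- i_dyn_frozen
      } else {
        i_dyn <- matrix(0, h, w)
        for (si in seq_len(s)) {
          t_sub <- ((t - 1) + (si - 1) / s) / params$fps
          v <- pulsation_velocity(t_sub, params$velocity,
                                  params$pulse_modulation,
                                  params$pulse_freq)
          rho <- decorrelation_factor(v, dt_sub,
                                      params$decorrelation_scale)
          if (rho < 1)
            amp <- rho * amp + sqrt(1 - rho^2) * field_noise(h, w, mask)
          i_dyn <- i_dyn + Mod(amp)^2
        }
        i_dyn <- i_dyn / s
      }
      dx <- params$translation_amplitude *
        sin(2 * pi * params$pulse_freq * (t - 1) / params$fps)
      frames[t, , ] <- render_intensity(i_dyn, i_stat, params, dx)
    }
    structure(list(frames = frames, fps = params$fps, params = params,
                   condition = condition, video_id = video_id),
              class = "speckle_video")
  })
}

#' @export
print.speckle_video <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("speckle_video '%s': %d frames of %dx%d px @ %g fps (%s)\n",
              x$video_id, d[1], d[2], d[3], x$fps,
              if (is.na(x$condition)) "unlabelled" else x$condition))
  invisible(x)
}

#' Default phantom measurement grid
#'
#' The (diameter, depth) cells of the phantom study: 3 mm vessels at 0,
#' 5 and 10 mm depth and 6 mm vessels at 0 and 5 mm.
#'
#' @return Data frame with columns `diameter_mm`, `depth_mm`.
#' @export
default_grid <- function() {
  data.frame(diameter_mm = c(3, 3, 3, 6, 6),
             depth_mm = c(0, 5, 10, 0, 5))
}

#' Simulate a full phantom dataset
#'
#' Generates `replicates` videos for every (diameter, depth) cell and
#' flow condition, with per-video velocities drawn uniformly from the
#' condition's velocity range.  The last replicate of each cell is
#' flagged `split = "test"` in the manifest, mirroring the acquisition
#' protocol in which the last-recorded video of each measurement is held
#' out.  Per-video seeds are derived from `(seed, video_id)` by a stable
#' hash, so the dataset is reproducible independently of generation
#' order.
#'
#' @param grid_spec Data frame of cells (`diameter_mm`, `depth_mm`);
#'   defaults to [default_grid()].
#' @param seed Master seed for the dataset.
#' @param replicates Videos per (cell, condition); the last is the test
#'   video.
#' @param out_dir If non-`NULL`, videos are written there as multi-page
#'   TIFFs with JSON sidecars and dropped from memory.
#' @param conditions Flow conditions to include.
#' @param ... Overrides passed to [simulation_params()] (e.g. `duration`,
#'   `height`).
#' @return A `phantom_dataset`: list with `videos` (named list, empty if
#'   `out_dir` was used) and `manifest` (data frame with columns
#'   video_id, diameter_mm, depth_mm, velocity_cm_s, condition, split,
#'   path, seed).
#' @export
make_phantom_dataset <- function(grid_spec = default_grid(), seed = 1L,
                                 replicates = 3L, out_dir = NULL,
                                 conditions = condition_levels(), ...) {
  if (is.null(grid_spec) || nrow(grid_spec) == 0L)
    stopf("grid_spec is empty: at least one (diameter, depth) cell is required")
  if (replicates < 2L)
    stopf("need at least 2 replicates per condition (train + test)")
  rows <- list()
  videos <- list()
  for (ci in seq_len(nrow(grid_spec))) {
    dia <- grid_spec$diameter_mm[ci]
    dep <- grid_spec$depth_mm[ci]
    for (cond in conditions) {
      for (rep_i in seq_len(replicates)) {
        vid <- sprintf("d%gmm_z%gmm_%s_r%d", dia, dep, tolower(cond), rep_i)
        vel <- with_seed(derive_seed(seed, "velocity", vid),
                         draw_condition_velocity(dia, cond))
        par <- simulation_params(velocity = vel, depth = dep,
                                 diameter = dia,
                                 seed = derive_seed(seed, "video", vid),
                                 ...)
        video <- simulate_video(par, condition = cond, video_id = vid)
        path <- NA_character_
        if (!is.null(out_dir)) {
          dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
          path <- file.path(out_dir, paste0(vid, ".tif"))
          write_video(video, path)
        } else {
          videos[[vid]] <- video
        }
        rows[[vid]] <- data.frame(
          video_id = vid, diameter_mm = dia, depth_mm = dep,
          velocity_cm_s = vel, condition = cond,
          split = if (rep_i == replicates) "test" else "train",
          path = path, seed = par$seed, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  structure(list(videos = videos, manifest = manifest),
            class = "phantom_dataset")
}
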