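test_that("simulation parameters are validated", {
  expect_error(simulation_params(velocity = -1), "velocity")
  expect_error(simulation_params(depth = 3), "depth")
  expect_error(simulation_params(diameter = 4), "diameter")
  expect_error(simulation_params(duration = 1 / 7), "integer frame count")
  expect_error(simulation_params(pulse_modulation = 1), "pulse_modulation")
  expect_error(simulation_params(exposure_substeps = 0), "exposure_substeps")
  # depth profile fills beta and blur
  p <- simulation_params(depth = 10)
  expect_equal(p$static_fraction, 0.7)
  expect_equal(p$blur_sigma, 2)
  # full profile reproduces the acquisition geometry
  pf <- simulation_params(profile = "full")
  expect_equal(round(pf$fps * pf$duration), 9900)
  expect_equal(c(pf$height, pf$width), c(224L, 224L))
})

test_that("rendered frames degrade as designed", {
  p <- tiny_params(velocity = 97, size = 128L, static_fraction = 0,
                   blur_sigma = 0, noise_sigma = 0,
                   translation_amplitude = 0, exposure_substeps = 1L)
  set.seed(9)
  stat <- generate_field(p)
  dyn <- generate_field(p)
  # no degradation: quantized fully developed speckle keeps unit contrast
  fr <- render_frame(list(dyn), stat, p)
  expect_true(all(fr >= 0 & fr <= 255))
  expect_equal(frame_contrast(fr), 1, tolerance = 0.05)
  expect_error(render_frame(list(), stat, p), "substep")

  # near-static limit: consecutive frames almost identical at high velocity
  ps <- tiny_params(velocity = 97, n_frames = 8L, seed = 21,
                    static_fraction = 0.97, noise_sigma = 0,
                    translation_amplitude = 0)
  v <- simulate_video(ps)
  r <- cor(as.vector(v$frames[1, , ]), as.vector(v$frames[2, , ]))
  expect_gt(r, 0.95)
})

test_that("spatial contrast falls monotonically with exposure substeps", {
  contrast_for_s <- function(s, seed) {
    p <- simulation_params(velocity = 97, height = 64, width = 64,
                           duration = 1 / 300, static_fraction = 0,
                           blur_sigma = 0, noise_sigma = 0,
                           translation_amplitude = 0,
                           exposure_substeps = s, seed = seed)
    set.seed(seed)
    stat <- generate_field(p)
    f <- generate_field(p)
    rho <- decorrelation_factor(97, 1 / (300 * s), p$decorrelation_scale)
    subs <- list(f)
    for (i in seq_len(s - 1)) subs[[i + 1]] <- evolve_field(subs[[i]], rho)
    frame_contrast(render_frame(subs, stat, p))
  }
  mean_k <- vapply(c(1, 2, 4, 8, 16), function(s)
    mean(vapply(1:10, function(seed) contrast_for_s(s, seed), numeric(1))),
    numeric(1))
  expect_true(all(diff(mean_k) < 0))
})

test_that("zero-flow video with no noise or translation is frozen", {
  p <- tiny_params(velocity = 0, n_frames = 6L, noise_sigma = 0,
                   translation_amplitude = 0, seed = 3)
  v <- simulate_video(p)
  for (t in 2:6)
    expect_identical(v$frames[t, , ], v$frames[1, , ])
})

test_that("identical parameters give bit-identical videos, seeds change them", {
  p <- tiny_params(velocity = 40, n_frames = 12L, seed = 8)
  v1 <- simulate_video(p)
  v2 <- simulate_video(p)
  expect_identical(v1$frames, v2$frames)
  p2 <- tiny_params(velocity = 40, n_frames = 12L, seed = 9)
  v3 <- simulate_video(p2)
  expect_false(identical(v1$frames, v3$frames))
  # same first-order statistics across seeds: mean intensity within 2%
  # (64-frame clips at 64 px, where the field-realisation fluctuation
  # of the video mean is a few tenths of a percent)
  pairs <- vapply(1:5, function(i) {
    a <- simulate_video(tiny_params(velocity = 40, n_frames = 64L,
                                    size = 64L, seed = 100 + i))
    b <- simulate_video(tiny_params(velocity = 40, n_frames = 64L,
                                    size = 64L, seed = 200 + i))
    mean(a$frames) / mean(b$frames)
  }, numeric(1))
  expect_true(all(abs(pairs - 1) < 0.02))
})

test_that("faster flow decorrelates the video more (Table 2 extremes)", {
  # 3 mm HIGH (83 cm/s) vs LOW (4.2 cm/s) on 64-frame clips
  hi <- simulate_video(tiny_params(velocity = 83, n_frames = 64L,
                                   size = 64L, seed = 51))
  lo <- simulate_video(tiny_params(velocity = 4.2, n_frames = 64L,
                                   size = 64L, seed = 52))
  expect_lt(lag1_autocorr(hi), lag1_autocorr(lo))
})

test_that("time-averaged contrast decreases with vessel depth", {
  k <- vapply(c(0, 5, 10), function(dep)
    video_mean_contrast(simulate_video(
      tiny_params(velocity = 40, depth = dep, n_frames = 16L,
                  size = 64L, seed = 61 + dep))), numeric(1))
  expect_true(all(diff(k) < 0))
})

test_that("phantom dataset has the right shape, labels and determinism", {
  grid <- data.frame(diameter_mm = 3, depth_mm = 0)
  ds <- make_phantom_dataset(grid, seed = 5, replicates = 3,
                             height = 16, width = 16,
                             duration = 8 / 300)
  expect_equal(nrow(ds$manifest), 12)           # 1 cell x 4 cond x 3
  expect_equal(sum(ds$manifest$split == "test"), 4)
  expect_setequal(unique(ds$manifest$condition), condition_levels())
  # velocities respect the condition ranges
  for (i in seq_len(nrow(ds$manifest))) {
    rng <- flow_conditions(3)
    rng <- rng[rng$condition == ds$manifest$condition[i], ]
    expect_gte(ds$manifest$velocity_cm_s[i], rng$vmin)
    expect_lte(ds$manifest$velocity_cm_s[i], rng$vmax)
  }
  # same seed reproduces manifest and frames
  ds2 <- make_phantom_dataset(grid, seed = 5, replicates = 3,
                              height = 16, width = 16,
                              duration = 8 / 300)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(ds$videos[[1]]$frames, ds2$videos[[1]]$frames)
  # full default grid arithmetic: 5 cells x 4 conditions x 3 replicates
  counts <- table(interaction(default_grid()$diameter_mm,
                              default_grid()$depth_mm))
  expect_equal(nrow(default_grid()) * 4 * 3, 60)
  expect_error(make_phantom_dataset(data.frame()), "empty")
})
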