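test_that("local contrast matches hand and brute-force computation", {
  # constant frame: every K = 0
  k0 <- local_contrast(matrix(100, 21, 21), window = 7)
  expect_true(all(k0$contrast_map == 0))
  expect_equal(k0$mean_contrast, 0)

  # hand case (population sd): values {1,1,1,1,3,3,3,3,2} have mu = 2,
  # sigma_pop = sqrt(8/9), so K = sqrt(8/9) / 2
  tile <- matrix(c(1, 1, 1, 1, 3, 3, 3, 3, 2), 3, 3)
  expect_equal(local_contrast(tile, 3)$mean_contrast, sqrt(8 / 9) / 2,
               tolerance = 1e-12)

  # brute-force per-window sigma/mu with explicit loops on a 21x21 frame
  set.seed(10)
  fr <- matrix(runif(21 * 21, 1, 255), 21, 21)
  res <- local_contrast(fr, window = 7)
  for (i in 1:3) {
    for (j in 1:3) {
      vals <- c()
      for (r in ((i - 1) * 7 + 1):(i * 7))
        for (cc in ((j - 1) * 7 + 1):(j * 7))
          vals <- c(vals, fr[r, cc])
      expect_equal(res$contrast_map[i, j],
                   sqrt(mean((vals - mean(vals))^2)) / mean(vals))
    }
  }
  expect_error(local_contrast(matrix(0, 21, 21)), "nonzero")
  expect_error(local_contrast(fr, window = 6), "odd")
  expect_error(local_contrast(matrix(1, 4, 4), window = 7), "smaller")
})

test_that("static fully developed speckle has near-unit window contrast", {
  # fine grains so a 7x7 tile samples many of them
  p <- simulation_params(height = 70, width = 70, duration = 1 / 300,
                         grain_radius = 1, static_fraction = 0,
                         blur_sigma = 0, noise_sigma = 0,
                         translation_amplitude = 0, exposure_substeps = 1L)
  ks <- vapply(1:6, function(s) {
    set.seed(500 + s)
    local_contrast(Mod(generate_field(p)$amplitude)^2, 7)$mean_contrast
  }, numeric(1))
  expect_equal(mean(ks), 1, tolerance = 0.1)
})

test_that("video contrast averages frames and falls with flow", {
  v <- simulate_video(tiny_params(velocity = 0, n_frames = 3L,
                                  noise_sigma = 0,
                                  translation_amplitude = 0, seed = 2))
  expect_equal(video_mean_contrast(v),
               local_contrast(v$frames[1, , ])$mean_contrast)
  # motion blur mechanism: high flow lowers K-bar vs zero flow
  hi <- simulate_video(tiny_params(velocity = 97, n_frames = 16L,
                                   size = 64L, seed = 3))
  zo <- simulate_video(tiny_params(velocity = 0, n_frames = 16L,
                                   size = 64L, seed = 4))
  expect_lt(video_mean_contrast(hi), video_mean_contrast(zo))
})

test_that("single-point calibration has the algebraic identities", {
  v <- simulate_video(tiny_params(velocity = 35, n_frames = 8L,
                                  size = 64L, seed = 6))
  cal <- calibrate_single_point(v, 28)
  expect_equal(cal$constant_A, 28 * cal$ref_contrast^2)
  # round trip: the reference video reads back its own velocity exactly
  expect_equal(estimate_velocity(cal, v), 28, tolerance = 1e-12)
  # K^2 scaling: doubling the contrast at fixed velocity quadruples A
  expect_equal((28 * (2 * cal$ref_contrast)^2) / cal$constant_A, 4)
  # worked numbers: A = 28 * 0.2^2 = 1.12; K = 0.1 reads 112 cm/s
  cal2 <- structure(list(constant_A = 28 * 0.2^2, ref_velocity = 28,
                         ref_contrast = 0.2, ref_depth = 0, window = 7L),
                    class = "lasca_calibration")
  expect_equal(cal2$constant_A, 1.12)
  expect_equal(1.12 / 0.2^2, 28)
  expect_equal(1.12 / 0.1^2, 112)
  expect_error(calibrate_single_point(v, 0), "known_velocity")
})

test_that("cross-depth table is complete and errors name missing depths", {
  ds <- make_phantom_dataset(data.frame(diameter_mm = 3,
                                        depth_mm = c(5, 10)),
                             seed = 3, replicates = 3,
                             conditions = "MEDIUM",
                             duration = 8 / 300)
  res <- cross_depth_experiment(ds, 10, c(5, 10))
  # bookkeeping: every nonzero-velocity video except the reference
  expect_equal(nrow(res$table), 5)
  expect_setequal(res$summary$depth_mm, c(5, 10))
  expect_error(cross_depth_experiment(ds, 0, 5), "depth 0")
})
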