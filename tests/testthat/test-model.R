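# small geometry used throughout: 16-cube inputs, 2 blocks
small_config <- function(n_classes = 4L, classes = condition_levels()) {
  model_config(input_shape = c(3L, 16L, 16L, 16L), stem_filters = 4L,
               block_channels = c(6L, 8L), head_hidden = 8L,
               n_classes = n_classes, classes = classes)
}

random_chunk <- function(seed, label = "ZERO", size = 16L) {
  set.seed(seed)
  list(frames = array(runif(size^3), c(size, size, size)),
       start_frame = 0L, video_id = paste0("v", seed), label = label)
}

test_that("cross-entropy matches closed forms and rejects bad shapes", {
  expect_equal(cross_entropy(c(0, 1, 0, 0), c(0, 1, 0, 0)), 0)
  expect_equal(cross_entropy(c(1, 0), c(0.5, 0.5)), log(2),
               tolerance = 1e-9)
  expect_equal(cross_entropy(c(0, 1, 0), c(0.2, 0.7, 0.1)), -log(0.7),
               tolerance = 1e-9)
  expect_error(cross_entropy(c(1, 0), c(1, 0, 0)), "shape")
  expect_error(cross_entropy(c(1, 0), c(0.9, 0.3)), "sum to 1")
})

test_that("cross-entropy gradient matches finite differences at random simplex points", {
  set.seed(88)
  for (i in 1:10) {
    n <- sample(2:6, 1)
    p <- as.vector(stats::rgamma(n, 1))
    p <- p / sum(p)
    t_idx <- sample(n, 1)
    truth <- replace(numeric(n), t_idx, 1)
    # analytic dL/dp_i = -t_i / p_i; perturb one coordinate pair to stay
    # on the simplex
    j <- if (t_idx == n) 1L else n
    eps <- 1e-6
    bump <- function(h) {
      q <- p
      q[t_idx] <- q[t_idx] + h
      q[j] <- q[j] - h
      cross_entropy(truth, q)
    }
    numeric_grad <- (bump(eps) - bump(-eps)) / (2 * eps)
    expect_lt(abs(numeric_grad - (-1 / p[t_idx])), 1e-4)
  }
})

test_that("model outputs are simplex vectors, deterministic and batch-stable", {
  m <- build_model(small_config(), seed = 3)
  chunks <- lapply(1:5, random_chunk)
  p1 <- predict_chunks(m, chunks)
  expect_equal(unname(rowSums(p1)), rep(1, 5), tolerance = 1e-5)
  expect_true(all(p1 >= 0))
  # deterministic in eval mode
  p2 <- predict_chunks(m, chunks)
  expect_identical(p1, p2)
  # batch order independence: permuted inputs give permuted outputs
  perm <- c(3, 1, 5, 2, 4)
  p3 <- predict_chunks(m, chunks[perm])
  expect_equal(p3, p1[perm, ], tolerance = 1e-12)
  # duplicated chunk gives identical rows
  p4 <- predict_chunks(m, chunks[c(1, 1)])
  expect_identical(p4[1, ], p4[2, ])
  # empty input, empty output
  expect_equal(nrow(predict_chunks(m, list())), 0)
  # wrong shape is refused
  expect_error(predict_chunks(m, list(random_chunk(1, size = 8L))),
               "shape")
})

test_that("architecture validation names the offending pooling stage", {
  cfg <- model_config(input_shape = c(3L, 8L, 8L, 8L), stem_filters = 4L,
                      block_channels = c(4L, 4L, 4L, 4L), head_hidden = 4L)
  expect_error(build_model(cfg), "pooling stage")
  expect_error(model_config(block_channels = c(32L, 16L)),
               "non-decreasing")
  expect_error(model_config(n_classes = 1L), "n_classes")
})

test_that("zero epochs is a no-op and missing classes are reported", {
  m <- build_model(small_config(), seed = 1)
  chunks <- lapply(1:8, function(i)
    random_chunk(i, label = condition_levels()[(i %% 4) + 1]))
  split <- structure(list(train = chunks, val = list(), test = list(),
                          split_seed = 1L), class = "dataset_split")
  fit0 <- train_model(m, split, train_config(epochs = 0))
  expect_identical(fit0$model, m)
  expect_equal(nrow(fit0$history), 0)
  split_bad <- split
  split_bad$train <- chunks[1:2]
  expect_error(train_model(m, split_bad, train_config(epochs = 1)),
               "missing class")
})

test_that("training is deterministic given the seed (full precision)", {
  chunks <- lapply(1:12, function(i)
    random_chunk(i, label = c("ZERO", "HIGH")[(i %% 2) + 1]))
  split <- structure(list(train = chunks[1:10], val = chunks[11:12],
                          test = list(), split_seed = 1L),
                     class = "dataset_split")
  cfg <- small_config(n_classes = 2L, classes = c("ZERO", "HIGH"))
  run <- function() {
    m <- build_model(cfg, seed = 5)
    train_model(m, split, train_config(batch_size = 4, epochs = 2,
                                       seed = 9))
  }
  f1 <- run()
  f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$layers[[1]]$w, f2$model$layers[[1]]$w)
})

test_that("half-precision rounding maps parameters onto the binary16 grid", {
  x <- c(0, 1, -1, 0.1, 1e-5, 65504, 1e6, pi)
  y <- speckleflow:::round_half_precision(x)
  expect_identical(y[1:3], c(0, 1, -1))
  expect_equal(y[4], 0.1, tolerance = 1e-3)
  expect_false(identical(y[4], 0.1))           # 0.1 is not representable
  expect_equal(y[8], pi, tolerance = 1e-3)
  expect_identical(y[6], 65504)                # largest finite half
  expect_identical(y[7], Inf)                  # overflow
  # idempotent
  expect_identical(speckleflow:::round_half_precision(y), y)
})

test_that("video-level voting is majority with ties to lower flow", {
  expect_equal(vote_video(c("HIGH", "HIGH", "LOW")), "HIGH")
  expect_equal(vote_video(c("ZERO", "HIGH")), "ZERO")
  expect_equal(vote_video("MEDIUM"), "MEDIUM")
  expect_equal(vote_video(c("LOW", "MEDIUM", "MEDIUM", "LOW")), "LOW")
  expect_error(vote_video(character(0)), "no chunk")
})
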