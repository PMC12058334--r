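test_that("confusion matrix counts truth/prediction pairs", {
  cm <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"),
                         classes = c("A", "B"))
  expect_equal(unname(cm), matrix(c(1L, 0L, 1L, 1L), 2, 2))
  # perfect predictions are diagonal with row sums = class counts
  truth <- rep(condition_levels(), times = c(3, 1, 4, 2))
  cmp <- confusion_matrix(truth, truth)
  expect_equal(unname(diag(cmp)), c(3L, 1L, 4L, 2L))
  expect_equal(sum(cmp) - sum(diag(cmp)), 0L)
  # empty input gives the all-zero matrix
  expect_true(all(confusion_matrix(character(0), character(0)) == 0L))
  expect_error(confusion_matrix("ZERO", c("ZERO", "LOW")), "length")
  expect_error(confusion_matrix("ZERO", "FOO"), "FOO")
})

test_that("report metrics agree with brute-force recomputation on random cases", {
  set.seed(12)
  for (i in 1:100) {
    n_cls <- sample(2:5, 1)
    classes <- LETTERS[seq_len(n_cls)]
    n <- sample(3:40, 1)
    truth <- sample(classes, n, replace = TRUE)
    pred <- sample(classes, n, replace = TRUE)
    rep <- report(confusion_matrix(truth, pred, classes))
    expect_equal(rep$accuracy, mean(truth == pred))
    expect_equal(rep$n_test, n)
    # row sums conserve true-class counts
    expect_equal(unname(rowSums(rep$confusion)),
                 unname(vapply(classes, function(cl)
                   sum(truth == cl), numeric(1))))
    cl <- sample(classes, 1)
    tp <- sum(truth == cl & pred == cl)
    prec <- if (sum(pred == cl) > 0) tp / sum(pred == cl) else 0
    rec <- if (sum(truth == cl) > 0) tp / sum(truth == cl) else 0
    row <- rep$per_class[rep$per_class$class == cl, ]
    expect_equal(row$precision, prec)
    expect_equal(row$recall, rec)
    expect_equal(row$f1,
                 if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
  }
})

test_that("report handles hand cases and degenerate classes", {
  cm <- matrix(c(8L, 2L, 2L, 8L), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  rep <- report(cm)
  expect_equal(rep$accuracy, 0.8)
  expect_equal(rep$per_class$precision, c(0.8, 0.8))
  expect_equal(rep$per_class$recall, c(0.8, 0.8))
  expect_equal(rep$per_class$f1, c(0.8, 0.8))
  # perfect diagonal
  repp <- report(diag(c(5L, 3L, 2L)))
  expect_equal(repp$accuracy, 1)
  expect_true(all(repp$per_class$f1 == 1))
  # a class never predicted: precision 0 with a flag, not a crash
  cm2 <- confusion_matrix(c("A", "B", "B"), c("B", "B", "B"),
                          classes = c("A", "B"))
  rep2 <- report(cm2)
  expect_equal(rep2$per_class$precision[1], 0)
  expect_true(rep2$per_class$degenerate[1])
  expect_error(report(matrix(0, 2, 2)), "empty")
})

test_that("merging zero and low coarsens labels and cannot lower accuracy", {
  expect_equal(merge_zero_low(c("ZERO", "LOW", "MEDIUM", "HIGH")),
               c("ZERO_LOW", "ZERO_LOW", "MEDIUM", "HIGH"),
               ignore_attr = TRUE)
  expect_length(unique(merge_zero_low(condition_levels())), 3)
  expect_error(merge_zero_low("NONE"), "unknown")
  set.seed(7)
  for (i in 1:50) {
    n <- sample(5:50, 1)
    truth <- sample(condition_levels(), n, replace = TRUE)
    pred <- sample(condition_levels(), n, replace = TRUE)
    acc4 <- mean(truth == pred)
    accm <- mean(merge_zero_low(truth) == merge_zero_low(pred))
    expect_gte(accm, acc4)
  }
})

test_that("run_report evaluates both schemes on identical predictions", {
  cfg <- model_config(input_shape = c(3L, 8L, 8L, 8L), stem_filters = 4L,
                      block_channels = c(4L, 6L), head_hidden = 8L)
  m <- build_model(cfg, seed = 2)
  set.seed(3)
  test_chunks <- lapply(1:10, function(i)
    list(frames = array(runif(8 * 8 * 8), c(8, 8, 8)), start_frame = 0L,
         video_id = paste0("t", i),
         label = condition_levels()[(i %% 4) + 1]))
  split <- structure(list(train = list(), val = list(),
                          test = test_chunks, split_seed = 1L),
                     class = "dataset_split")
  dir <- withr::local_tempdir()
  out <- run_report(split, m, out_dir = dir)
  expect_equal(out$four_class$n_test, 10)
  expect_equal(out$merged$n_test, 10)
  expect_gte(out$merged$accuracy, out$four_class$accuracy)
  expect_equal(nrow(out$predictions), 10)
  expect_true(file.exists(file.path(dir, "confusion_four_class.csv")))
  expect_true(file.exists(file.path(dir, "confusion_merged.png")))
  # empty variant list defaults to the 4-class scheme
  out2 <- run_report(split, m, variants = character(0))
  expect_named(out2, c("predictions", "four_class"))
  expect_error(run_report(structure(list(test = list()),
                                    class = "dataset_split"), m),
               "test split")
})
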