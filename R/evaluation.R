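#' Confusion matrix
#'
#' Entry `(i, j)` counts samples of true class `i` predicted as class
#' `j`.
#'
#' @param true_labels,pred_labels Equal-length label vectors.
#' @param classes Class labels fixing row/column order.
#' @return Square integer matrix with `classes` as dimnames.
#' @export
confusion_matrix <- function(true_labels, pred_labels,
                             classes = condition_levels()) {
  if (length(true_labels) != length(pred_labels))
    stopf("true (%d) and predicted (%d) label vectors differ in length",
          length(true_labels), length(pred_labels))
  bad <- setdiff(unique(c(true_labels, pred_labels)), classes)
  if (length(bad) > 0L)
    stopf("labels outside the class set: %s", paste(bad, collapse = ", "))
  cm <- table(factor(true_labels, levels = classes),
              factor(pred_labels, levels = classes))
  matrix(as.integer(cm), length(classes), length(classes),
         dimnames = list(true = classes, predicted = classes))
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy (trace over total) plus one-vs-rest precision, recall and
#' F1 per class, and their macro averages.  A metric with a zero
#' denominator (a class never predicted, or absent from the test set)
#' is reported as 0 and flagged `degenerate` rather than propagating
#' `NaN`.
#'
#' @param confusion Square count matrix, rows = true, columns =
#'   predicted.
#' @return A `classification_report`: list with `confusion`, `accuracy`,
#'   `per_class` (data frame: class, precision, recall, f1, degenerate),
#'   `macro` (named vector) and `n_test`.
#' @export
report <- function(confusion) {
  if (!is.matrix(confusion) || nrow(confusion) != ncol(confusion))
    stopf("confusion must be a square matrix")
  total <- sum(confusion)
  if (total == 0) stopf("empty confusion matrix: no test samples")
  classes <- rownames(confusion)
  if (is.null(classes)) classes <- as.character(seq_len(nrow(confusion)))
  diagv <- diag(confusion)
  colsum <- colSums(confusion)
  rowsum <- rowSums(confusion)
  degenerate <- colsum == 0 | rowsum == 0
  precision <- ifelse(colsum > 0, diagv / colsum, 0)
  recall <- ifelse(rowsum > 0, diagv / rowsum, 0)
  pr <- precision + recall
  f1 <- ifelse(pr > 0, 2 * precision * recall / pr, 0)
  per_class <- data.frame(class = classes, precision = precision,
                          recall = recall, f1 = f1,
                          degenerate = degenerate,
                          row.names = NULL, stringsAsFactors = FALSE)
  structure(list(confusion = confusion,
                 accuracy = sum(diagv) / total,
                 per_class = per_class,
                 macro = c(precision = mean(precision),
                           recall = mean(recall), f1 = mean(f1)),
                 n_test = total),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("classification_report: accuracy %.4f on %d samples\n",
              x$accuracy, x$n_test))
  print(x$confusion)
  print(x$per_class, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Merge the zero- and low-flow classes
#'
#' Relabels a 4-class sequence onto 3 classes by collapsing `ZERO` and
#' `LOW` into `ZERO_LOW` (both are clinically "compromised flow");
#' `MEDIUM` and `HIGH` are preserved.  Coarsening the label space this
#' way can only keep or raise accuracy for a fixed set of predictions.
#'
#' @param labels Character vector of 4-class labels.
#' @return Character vector over `c("ZERO_LOW", "MEDIUM", "HIGH")`, with
#'   the mapping table attached as attribute `mapping`.
#' @export
merge_zero_low <- function(labels) {
  mapping <- c(ZERO = "ZERO_LOW", LOW = "ZERO_LOW",
               MEDIUM = "MEDIUM", HIGH = "HIGH")
  bad <- setdiff(unique(labels), names(mapping))
  if (length(bad) > 0L)
    stopf("unknown label(s): %s", paste(bad, collapse = ", "))
  out <- unname(mapping[labels])
  attr(out, "mapping") <- mapping
  out
}

#' Merged-scheme class labels
#' @return `c("ZERO_LOW", "MEDIUM", "HIGH")`.
#' @export
merged_levels <- function() c("ZERO_LOW", "MEDIUM", "HIGH")

#' Evaluate a trained model on the test split
#'
#' Predicts every test chunk once and scores the 4-class scheme and,
#' optionally, the merged zero+low scheme on those identical
#' predictions.  Optionally writes per-variant report CSVs and confusion
#' heatmap PNGs.
#'
#' @param split A `dataset_split` with a non-empty test set.
#' @param model A trained `flow_model`.
#' @param variants Character subset of `c("four_class", "merged")`;
#'   empty defaults to `"four_class"`.
#' @param out_dir If non-`NULL`, reports are written under it.
#' @return Named list of `classification_report`s (one per variant)
#'   plus `predictions` (data frame: video_id, start_frame, true,
#'   predicted).
#' @export
run_report <- function(split, model, variants = c("four_class", "merged"),
                       out_dir = NULL) {
  if (length(split$test) == 0L)
    stopf("test split is empty: nothing to evaluate")
  if (length(variants) == 0L) variants <- "four_class"
  variants <- match.arg(variants, c("four_class", "merged"),
                        several.ok = TRUE)
  probs <- predict_chunks(model, split$test)
  classes <- model$config$classes
  pred <- classes[max.col(probs, ties.method = "first")]
  truth <- vapply(split$test, `[[`, "", "label")
  predictions <- data.frame(
    video_id = vapply(split$test, `[[`, "", "video_id"),
    start_frame = vapply(split$test, function(ch) ch$start_frame, 0),
    true = truth, predicted = pred, stringsAsFactors = FALSE)
  out <- list(predictions = predictions)
  for (v in variants) {
    if (v == "four_class") {
      cm <- confusion_matrix(truth, pred, classes)
    } else {
      cm <- confusion_matrix(merge_zero_low(truth), merge_zero_low(pred),
                             merged_levels())
    }
    rep <- report(cm)
    out[[v]] <- rep
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(as.data.frame.matrix(rep$confusion),
                       file.path(out_dir, paste0("confusion_", v, ".csv")))
      utils::write.csv(cbind(rep$per_class,
                             accuracy = rep$accuracy, n_test = rep$n_test),
                       file.path(out_dir, paste0("report_", v, ".csv")),
                       row.names = FALSE)
      plot_confusion(rep$confusion,
                     file.path(out_dir, paste0("confusion_", v, ".png")))
    }
  }
  out
}

# confusion-matrix heatmap (counts annotated)
plot_confusion <- function(confusion, path) {
  grDevices::png(path, width = 640, height = 560)
  on.exit(grDevices::dev.off())
  n <- nrow(confusion)
  graphics::image(seq_len(n), seq_len(n),
                  t(confusion[n:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(32, "Blues 3", rev = TRUE),
                  axes = FALSE, xlab = "predicted", ylab = "true",
                  main = "Confusion matrix")
  graphics::axis(1, seq_len(n), colnames(confusion))
  graphics::axis(2, seq_len(n), rev(rownames(confusion)), las = 2)
  for (i in seq_len(n))
    for (j in seq_len(n))
      graphics::text(j, n - i + 1, confusion[i, j])
  invisible(path)
}
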