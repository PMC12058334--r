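#' Normalize 8-bit frames to [0, 1]
#'
#' Exact division by 255, preserving shape; multiplying back by 255 and
#' rounding recovers the original gray values bit for bit.
#'
#' @param frames Numeric/integer array of gray values in [0, 255].
#' @return Double array of the same shape with values in [0, 1].
#' @export
normalize_frames <- function(frames) {
  if (inherits(frames, "speckle_video")) frames <- frames$frames
  frames / 255
}

#' Split a video into fixed-length temporal chunks
#'
#' Sliding windows of `size` consecutive frames advancing by `stride`;
#' only complete windows are emitted, so the chunk count is
#' `floor((T - size) / stride) + 1` for `T >= size` and 0 otherwise
#' (with a warning, not an error, for too-short videos).
#'
#' @param frames T x H x W array (or a `speckle_video`).
#' @param size Frames per chunk (default 64).
#' @param stride Frame offset between consecutive chunk starts
#'   (default 32; overlapping chunks enlarge the training set).
#' @return List of chunks; each chunk is a list with `frames`
#'   (size x H x W, same value scale as the input) and 0-based
#'   `start_frame`.
#' @export
chunk_video <- function(frames, size = 64L, stride = 32L) {
  if (inherits(frames, "speckle_video")) frames <- frames$frames
  if (size < 1L || stride < 1L)
    stopf("size and stride must be >= 1 (got %d, %d)", size, stride)
  n <- dim(frames)[1]
  starts <- chunk_starts(n, size, stride)
  if (length(starts) == 0L) {
    warning(sprintf("video has %d frames, shorter than one %d-frame chunk: no chunks emitted",
                    n, size), call. = FALSE)
    return(list())
  }
  lapply(starts, function(s0)
    list(frames = frames[(s0 + 1):(s0 + size), , , drop = FALSE],
         start_frame = s0))
}

# 0-based chunk start indices
chunk_starts <- function(n_frames, size, stride) {
  if (n_frames < size) return(integer(0))
  seq(0L, n_frames - size, by = stride)
}

#' Replicate a single-channel chunk to three channels
#'
#' The grayscale chunk is repeated across three identical channels to
#' match the RGB input convention of video-classification backbones; no
#' value changes.
#'
#' @param chunk T x H x W array of one chunk's frames.
#' @return 3 x T x H x W array with three identical channels.
#' @export
to_three_channel <- function(chunk) {
  d <- dim(chunk)
  if (length(d) != 3L)
    stopf("expected a single-channel T x H x W chunk, got %d dimensions",
          length(d))
  array(rep(as.vector(chunk), each = 3L), dim = c(3L, d))
}

#' Extract labelled, normalized chunks from a dataset
#'
#' Normalizes every video ([normalize_frames()]) and chunks it
#' ([chunk_video()]); each chunk carries its source video's label and
#' identity so that splits can be built without leakage.
#'
#' @param dataset A `phantom_dataset` (videos must be in memory; use
#'   [load_dataset()] for datasets written to disk).
#' @param size,stride Chunking geometry, see [chunk_video()].
#' @return List of chunk objects: `frames` (size x H x W in [0, 1]),
#'   `start_frame`, `video_id`, `label`.
#' @export
make_chunks <- function(dataset, size = 64L, stride = 32L) {
  chunks <- list()
  for (vid in names(dataset$videos)) {
    video <- dataset$videos[[vid]]
    vchunks <- chunk_video(normalize_frames(video), size, stride)
    for (ch in vchunks) {
      ch$video_id <- vid
      ch$label <- video$condition
      chunks[[length(chunks) + 1L]] <- ch
    }
  }
  chunks
}

#' Build the train/validation/test split
#'
#' All chunks of the manifest's test videos (the last-recorded video of
#' each measurement cell) form the test set; the remaining chunks are
#' shuffled with `split_seed` and 10% of them become the validation
#' set.  Leakage control is at video level: no video contributes chunks
#' to both test and train/validation.
#'
#' @param chunks Chunk list from [make_chunks()].
#' @param manifest Dataset manifest with `video_id`, `split`,
#'   `diameter_mm`, `depth_mm`, `condition` columns.
#' @param split_seed Integer seed for the validation draw.
#' @param val_fraction Fraction of training chunks held out for
#'   validation (default 0.10).
#' @return A `dataset_split`: list with `train`, `val`, `test` chunk
#'   lists and `split_seed`; each chunk gains a `split` field.
#' @export
build_split <- function(chunks, manifest, split_seed = 1L,
                        val_fraction = 0.10) {
  cell <- interaction(manifest$diameter_mm, manifest$depth_mm,
                      manifest$condition, drop = TRUE)
  for (cl in levels(cell)) {
    n_cell <- sum(cell == cl)
    if (n_cell < 2L)
      stopf("measurement cell %s has %d video(s); at least 2 (train + test) are required",
            cl, n_cell)
  }
  test_ids <- manifest$video_id[manifest$split == "test"]
  is_test <- vapply(chunks, function(ch) ch$video_id %in% test_ids,
                    logical(1))
  test <- chunks[is_test]
  pool <- chunks[!is_test]
  perm <- with_seed(split_seed, sample.int(length(pool)))
  n_val <- round(val_fraction * length(pool))
  val_idx <- perm[seq_len(n_val)]
  val <- pool[val_idx]
  train <- pool[setdiff(perm, val_idx)]
  tag <- function(lst, s) lapply(lst, function(ch) { ch$split <- s; ch })
  structure(list(train = tag(train, "train"), val = tag(val, "val"),
                 test = tag(test, "test"), split_seed = split_seed),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("dataset_split: %d train / %d val / %d test chunks (seed %d)\n",
              length(x$train), length(x$val), length(x$test),
              x$split_seed))
  invisible(x)
}
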