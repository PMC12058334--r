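#' Write a speckle video as a multi-page TIFF with a JSON sidecar
#'
#' One 8-bit grayscale page per frame; acquisition metadata (simulation
#' parameters, condition, id) goes to `<path>.json` next to the TIFF so
#' the round trip through [read_video()] is lossless.
#'
#' @param video A `speckle_video`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_video <- function(video, path) {
  stopifnot(inherits(video, "speckle_video"))
  pages <- lapply(seq_len(dim(video$frames)[1]),
                  function(t) video$frames[t, , ] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  meta <- list(params = unclass(video$params),
               condition = video$condition,
               video_id = video$video_id,
               fps = video$fps)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Read a speckle video written by [write_video()]
#'
#' @param path TIFF path.
#' @return The reconstructed `speckle_video` (frames bit-identical to
#'   what was written).
#' @export
read_video <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stopf("'%s' is not a readable TIFF: %s", path,
                            conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0L, dim = c(length(pages), nrow(pages[[1]]),
                              ncol(pages[[1]])))
  for (t in seq_along(pages)) frames[t, , ] <- as.integer(pages[[t]])
  meta_path <- sidecar_path(path)
  params <- NULL
  condition <- NA_character_
  video_id <- tools::file_path_sans_ext(basename(path))
  fps <- NA_real_
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    params <- structure(meta$params, class = "simulation_params")
    if (!is.null(meta$condition)) condition <- meta$condition
    if (!is.null(meta$video_id)) video_id <- meta$video_id
    if (!is.null(meta$fps)) fps <- meta$fps
  }
  structure(list(frames = frames, fps = fps, params = params,
                 condition = condition, video_id = video_id),
            class = "speckle_video")
}

#' Write / read a dataset manifest
#'
#' @param manifest Manifest data frame (see [make_phantom_dataset()]).
#' @param path CSV path.
#' @return `write_manifest`: `path` invisibly; `read_manifest`: the
#'   manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Load the videos of a dataset written to disk
#'
#' @param manifest Manifest with a `path` column.
#' @return A `phantom_dataset` with videos in memory.
#' @export
load_dataset <- function(manifest) {
  videos <- lapply(manifest$path, read_video)
  names(videos) <- manifest$video_id
  structure(list(videos = videos, manifest = manifest),
            class = "phantom_dataset")
}
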