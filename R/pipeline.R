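#' Experiment configuration
#'
#' Bundles every tunable of the pipeline under one master seed.
#' Stage-level and per-video seeds are derived from `master_seed` by a
#' stable hash, so a config fully determines the run.
#'
#' @param master_seed Integer master seed (required).
#' @param grid Measurement grid data frame (`diameter_mm`, `depth_mm`).
#' @param conditions Flow conditions simulated per cell.
#' @param replicates Videos per (cell, condition); last is the test
#'   video.
#' @param simulation Named list of [simulation_params()] overrides.
#' @param chunk_size,chunk_stride Chunking geometry (frames).
#' @param val_fraction Validation fraction of training chunks.
#' @param model Named list of [model_config()] overrides.
#' @param train Named list of [train_config()] overrides.
#' @param lasca List with `window`, `calibration_depth`, `test_depths`.
#' @param out_dir Output directory for all artifacts.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(master_seed,
                              grid = default_grid(),
                              conditions = condition_levels(),
                              replicates = 3L,
                              simulation = list(),
                              chunk_size = 64L,
                              chunk_stride = 32L,
                              val_fraction = 0.10,
                              model = list(),
                              train = list(),
                              lasca = list(window = 7L,
                                           calibration_depth = 10,
                                           test_depths = c(5, 10)),
                              out_dir = "speckleflow_run") {
  if (missing(master_seed) || is.null(master_seed))
    stopf("master_seed is required")
  check_number(master_seed, "master_seed")
  grid <- as.data.frame(grid)
  if (!all(c("diameter_mm", "depth_mm") %in% names(grid)))
    stopf("grid must have diameter_mm and depth_mm columns")
  if (chunk_size < 1L) stopf("chunk_size must be >= 1, got %g", chunk_size)
  if (chunk_stride < 1L)
    stopf("chunk_stride must be >= 1, got %g", chunk_stride)
  check_number(val_fraction, "val_fraction", lower = 0, upper = 1)
  # validate overrides eagerly so a bad config fails at load time
  do.call(simulation_params, simulation)
  do.call(model_config, model)
  do.call(train_config, train)
  structure(list(master_seed = as.integer(master_seed), grid = grid,
                 conditions = conditions,
                 replicates = as.integer(replicates),
                 simulation = simulation,
                 chunk_size = as.integer(chunk_size),
                 chunk_stride = as.integer(chunk_stride),
                 val_fraction = val_fraction,
                 model = model, train = train, lasca = lasca,
                 out_dir = out_dir),
            class = "experiment_config")
}

#' Load / save an experiment configuration
#'
#' YAML round trip for [experiment_config()]; unknown keys are rejected
#' by name and all sub-configs are validated at load time.
#'
#' @param path YAML file path.
#' @return `load_config`: the validated `experiment_config`;
#'   `save_config`: `path`, invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("no such config file: %s", path)
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(experiment_config)), "")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L)
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  if (!is.null(raw$grid))
    raw$grid <- do.call(rbind, lapply(raw$grid, as.data.frame))
  do.call(experiment_config, raw)
}

#' @rdname load_config
#' @param config An `experiment_config`.
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  x$grid <- lapply(seq_len(nrow(config$grid)), function(i)
    as.list(config$grid[i, ]))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Run the full phantom pipeline
#'
#' Executes the requested stages in order -- simulate, preprocess,
#' train, evaluate, lasca -- with per-stage seeds derived from the
#' master seed, writing every artifact under `config$out_dir`.  Stages
#' that depend on earlier in-memory state reload it from the on-disk
#' artifacts when run in a fresh session.
#'
#' @param config An [experiment_config()].
#' @param stages Subset of `c("simulate", "preprocess", "train",
#'   "evaluate", "lasca")`.
#' @return A `run_record`: config snapshot, per-stage timings, artifact
#'   paths, and the failing stage (if any).
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "preprocess", "train",
                                    "evaluate", "lasca")) {
  stopifnot(inherits(config, "experiment_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  record <- list(config = config,
                 version = as.character(utils::packageVersion("speckleflow")),
                 timings = list(), artifacts = list(),
                 failed_stage = NULL)
  state <- new.env(parent = emptyenv())
  manifest_path <- file.path(out, "manifest.csv")

  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    ok <- tryCatch({ fun(); TRUE },
                   error = function(e) {
                     record$failed_stage <<- list(stage = name,
                                                  message = conditionMessage(e))
                     FALSE
                   })
    record$timings[[name]] <<- proc.time()[["elapsed"]] - t0
    ok
  }

  need_dataset <- function() {
    if (is.null(state$dataset)) {
      if (!file.exists(manifest_path))
        stopf("no dataset: run the simulate stage first")
      state$dataset <- load_dataset(read_manifest(manifest_path))
    }
    state$dataset
  }
  need_split <- function() {
    if (is.null(state$split)) {
      ds <- need_dataset()
      chunks <- make_chunks(ds, config$chunk_size, config$chunk_stride)
      state$split <- build_split(chunks, ds$manifest,
                                 derive_seed(config$master_seed, "split"),
                                 config$val_fraction)
    }
    state$split
  }

  for (stage in stages) {
    ok <- switch(stage,
      simulate = run_stage("simulate", function() {
        ds <- do.call(make_phantom_dataset, c(
          list(grid_spec = config$grid,
               seed = derive_seed(config$master_seed, "simulate"),
               replicates = config$replicates,
               out_dir = file.path(out, "videos"),
               conditions = config$conditions),
          config$simulation))
        write_manifest(ds$manifest, manifest_path)
        record$artifacts$manifest <<- manifest_path
        record$artifacts$videos <<- file.path(out, "videos")
        state$dataset <- NULL      # force reload with paths
      }),
      preprocess = run_stage("preprocess", function() {
        split <- need_split()
        index <- lapply(c(train = "train", val = "val", test = "test"),
                        function(s) lapply(split[[s]], function(ch)
                          list(video_id = ch$video_id,
                               start_frame = ch$start_frame,
                               label = ch$label, split = s)))
        path <- file.path(out, "chunk_index.json")
        jsonlite::write_json(index, path, auto_unbox = TRUE)
        record$artifacts$chunk_index <<- path
      }),
      train = run_stage("train", function() {
        split <- need_split()
        d <- dim(split$train[[1]]$frames)
        mov <- config$model
        if (is.null(mov$input_shape)) mov$input_shape <- c(3L, d)
        mcfg <- do.call(model_config, mov)
        tcfg <- do.call(train_config, c(
          list(seed = derive_seed(config$master_seed, "train")),
          config$train))
        model <- build_model(mcfg, seed = tcfg$seed)
        fit <- train_model(model, split, tcfg)
        state$model <- fit$model
        hpath <- file.path(out, "train_history.csv")
        utils::write.csv(fit$history, hpath, row.names = FALSE)
        cpath <- file.path(out, "model.rds")
        saveRDS(fit$model, cpath)
        jsonlite::write_json(list(model = unclass(mcfg)[
          c("profile", "input_shape", "stem_filters", "block_channels",
            "head_hidden", "n_classes", "classes")],
          train = unclass(tcfg)),
          file.path(out, "model_config.json"), auto_unbox = TRUE)
        record$artifacts$history <<- hpath
        record$artifacts$model <<- cpath
      }),
      evaluate = run_stage("evaluate", function() {
        if (is.null(state$model)) {
          cpath <- file.path(out, "model.rds")
          if (!file.exists(cpath))
            stopf("no trained model: run the train stage first")
          state$model <- readRDS(cpath)
        }
        rep_dir <- file.path(out, "reports")
        run_report(need_split(), state$model, out_dir = rep_dir)
        record$artifacts$reports <<- rep_dir
      }),
      lasca = run_stage("lasca", function() {
        ds <- need_dataset()
        res <- cross_depth_experiment(
          ds, config$lasca$calibration_depth, config$lasca$test_depths,
          window = config$lasca$window)
        path <- file.path(out, "lasca_cross_depth.csv")
        utils::write.csv(res$table, path, row.names = FALSE)
        record$artifacts$lasca <<- path
      }))
    if (!ok) break
  }
  rpath <- file.path(out, "run_record.json")
  jsonlite::write_json(
    list(version = record$version, timings = record$timings,
         artifacts = record$artifacts, failed_stage = record$failed_stage,
         master_seed = config$master_seed),
    rpath, auto_unbox = TRUE)
  save_config(config, file.path(out, "config.yaml"))
  record$record_path <- rpath
  structure(record, class = "run_record")
}

#' @export
print.run_record <- function(x, ...) {
  cat("run_record\n")
  for (nm in names(x$timings))
    cat(sprintf("  %-10s %8.2f s\n", nm, x$timings[[nm]]))
  if (!is.null(x$failed_stage))
    cat(sprintf("  FAILED at %s: %s\n", x$failed_stage$stage,
                x$failed_stage$message))
  invisible(x)
}
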