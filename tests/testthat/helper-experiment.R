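# Desk-scale reference experiment, memoised so the depth-comparison test
# can reuse the depth-0 training instead of repeating it.  One
# measurement cell, velocities drawn from the four condition ranges,
# three 224-frame videos per condition (2 train / 1 test), the full
# training recipe.

.experiment_cache <- new.env(parent = emptyenv())

desk_experiment <- function(depth, master_seed = 101L) {
  key <- paste0("d", depth, "_s", master_seed)
  if (!is.null(.experiment_cache[[key]])) return(.experiment_cache[[key]])
  out_dir <- file.path(tempdir(), paste0("speckleflow_", key))
  cfg <- experiment_config(
    master_seed = master_seed,
    grid = data.frame(diameter_mm = 3, depth_mm = depth),
    simulation = list(duration = 224 / 300),
    out_dir = out_dir)
  rec <- run_pipeline(cfg, stages = c("simulate", "preprocess", "train",
                                      "evaluate"))
  stopifnot(is.null(rec$failed_stage))
  res <- list(
    record = rec,
    four_class = utils::read.csv(file.path(out_dir, "reports",
                                           "report_four_class.csv")),
    merged = utils::read.csv(file.path(out_dir, "reports",
                                       "report_merged.csv")),
    history = utils::read.csv(file.path(out_dir, "train_history.csv")))
  .experiment_cache[[key]] <- res
  res
}
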