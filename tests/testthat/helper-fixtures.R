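# Shared fixtures: everything is generated in code at test time.

# quick simulation parameter sets for small videos
tiny_params <- function(velocity = 0, depth = 0, n_frames = 32L,
                        size = 32L, seed = 1L, ...) {
  simulation_params(velocity = velocity, depth = depth,
                    height = size, width = size,
                    duration = n_frames / 300, seed = seed, ...)
}

# fabricated chunk carrying metadata only (1-frame payload), for split
# arithmetic tests that do not touch the model
fake_chunk <- function(video_id, label, start_frame = 0L) {
  list(frames = array(0, c(1L, 1L, 1L)), start_frame = start_frame,
       video_id = video_id, label = label)
}

# manifest row block for one measurement cell
fake_manifest <- function(video_ids, condition, diameter = 3, depth = 0,
                          test_last = TRUE) {
  n <- length(video_ids)
  data.frame(video_id = video_ids, diameter_mm = diameter,
             depth_mm = depth, velocity_cm_s = 10, condition = condition,
             split = c(rep("train", n - test_last), rep("test", test_last)),
             path = NA_character_, seed = seq_len(n),
             stringsAsFactors = FALSE)
}

# chunk list for a video: n chunks with consecutive starts
fake_video_chunks <- function(video_id, label, n, stride = 32L) {
  lapply(seq_len(n) - 1L, function(i)
    fake_chunk(video_id, label, i * stride))
}

with_seed_local <- function(seed, expr) {
  set.seed(seed)
  expr
}
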