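# speckleflow

Simulation and classification of dynamic laser-speckle recordings from
arterial flow phantoms.

When coherent light hits tissue over a blood vessel, the backscattered
speckle pattern fluctuates at a rate set by the flow underneath.  A
defocused high-speed camera turns those fluctuations into video, and
two readouts can be built on top: a **3D convolutional network** that
classifies raw 64-frame video chunks into four flow states — zero
(full occlusion, the ischemic-stroke condition), low (pre-stroke),
medium and high — and classical **LASCA** (laser speckle contrast
analysis), which maps spatial contrast $K = \sigma/\mu$ to velocity
through a single-point calibration $V = A/K^2$.

`speckleflow` implements the whole bench in R:

* a **physically grounded simulator** of defocused dynamic-speckle
  videos: band-limited circular complex Gaussian fields (fully
  developed speckle, negative-exponential intensity, unit contrast),
  autoregressive field decorrelation with correlation time
  $\tau_c = k_v/v$, 1 Hz pulsatile modulation, exposure integration,
  depth-dependent static scattering and blur, sensor noise and 8-bit
  quantization — for 3 and 6 mm vessels at 0/5/10 mm depth with the
  four condition velocity ranges;
* the **preprocessing** used for training: division by 255, 64-frame
  chunks at stride 32, three-channel replication, video-level
  train/validation/test splits with the last-recorded video of each
  measurement held out;
* a **3D CNN classifier** (conv–batchnorm–ReLU stem and blocks with
  max pooling, global average pooling, dense softmax head) trained
  from scratch with Adam (lr 0.001), batch size 8, 20 epochs,
  categorical cross-entropy — with conv/pool kernels in
  RcppArmadillo so desk-scale training runs on one CPU in minutes;
* the **LASCA baseline** with single-point calibration and the
  cross-depth calibration-transfer experiment showing where the
  $V \propto 1/K^2$ readout breaks down;
* **evaluation**: confusion matrices, per-class and macro
  precision/recall/F1, the merged zero+low labelling variant, and a
  seeded end-to-end pipeline (`run_pipeline()`, plus a thin CLI in
  `inst/cli/speckleflow`).

## A worked example

```r
library(speckleflow)

lo <- simulate_video(simulation_params(velocity = 5.5, depth = 0,
                                       duration = 64/300, seed = 1),
                     condition = "LOW", video_id = "low1")
hi <- simulate_video(simulation_params(velocity = 97, depth = 0,
                                       duration = 64/300, seed = 2),
                     condition = "HIGH", video_id = "high1")
lo
#> speckle_video 'low1': 64 frames of 64x64 px @ 300 fps (LOW)

lag1_autocorr(lo); lag1_autocorr(hi)
#> lag-1 autocorrelation: low 0.833, high 0.121
video_mean_contrast(lo); video_mean_contrast(hi)
#> mean speckle contrast: low 0.705, high 0.498
```

Low flow barely decorrelates the field between frames (lag-1
autocorrelation 0.83) while high flow scrambles it (0.12), and the
within-exposure motion blur of fast flow lowers the spatial contrast
from 0.71 to 0.50 — the two signatures the classifier and LASCA
exploit, respectively.

```r
ref <- simulate_video(simulation_params(velocity = 40.5, depth = 0,
                                        duration = 64/300, seed = 3))
cal <- calibrate_single_point(ref, 40.5, ref_depth = 0)
cal
#> lasca_calibration: A = 14.21 (V_ref 40.5 cm/s, K_ref 0.5924, depth 0 mm)

test <- simulate_video(simulation_params(velocity = 30, depth = 0,
                                         duration = 64/300, seed = 4))
estimate_velocity(cal, test)
#> true 30 cm/s -> LASCA estimate 37.0 cm/s
```

A same-depth, same-condition estimate lands within the expected
10–20% band.  Calibrating at 10 mm depth and applying the constant at
5 mm instead produces errors several times larger
(`cross_depth_experiment()`), because the depth-dependent static
scattering and blur shift the whole contrast scale — the failure mode
that motivates the calibration-free classifier.

A complete seeded experiment — simulate a phantom grid, preprocess,
train, evaluate, run LASCA — is one call:

```r
cfg <- experiment_config(master_seed = 11,
                         grid = data.frame(diameter_mm = 3, depth_mm = 0),
                         simulation = list(duration = 224/300),
                         out_dir = "run11")
run_pipeline(cfg)
```

which writes the manifest, TIFF videos, chunk index, training history,
model checkpoint, report CSVs and confusion heatmaps under `run11/`.
At this desk scale (64×64 px, 224-frame videos, reduced channels) the
classifier reaches 80–100% held-out chunk accuracy against a 25%
chance level.

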