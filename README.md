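# mmhar — multimodal human locomotion decoding

`mmhar` decodes activities of daily living (lying down, standing, walking,
running, …) from synchronized multimodal recordings: a body-worn inertial
measurement unit (tri-axial accelerometer, gyroscope, magnetometer), a set
of ambient binary sensors (switches, PIR detectors) with a known adjacency
layout, and a low-resolution video of the subject. It is aimed at
researchers in wearable-sensor activity recognition who want a fully
tested, deterministic reference pipeline whose every stage can be validated
against exact ground truth.

The pipeline:

1. **Quaternion-based IMU filtration** — zero-phase Butterworth split with
   the combined channel norm `√(ΣLPFᵢ² + ΣHPFᵢ²)`, gravity estimation
   (`gm`, `ga`) and removal, hard-iron magnetic correction, db4 wavelet
   denoising of the gyroscope, and orientation fusion
   `q̇ = ½ q ⊗ (0, ω)` with a gradient-descent correction toward the
   gravity and magnetic reference directions; Euler angles
   `A_xz = atan2(z, x)`, `A_yz = atan2(z, y)`, `A_xy = atan2(y, x)`.
2. **Vision preprocessing** — frame striding, per-pixel median background,
   subtraction mask, and blob/centroid skeleton modelling into 12 landmarks
   across 7 categories with per-category confidence.
3. **Segmentation** — overlapped time windows (W = 2 s, 50 % overlap) for
   motion/ambient, displacement change-point event segments for vision.
4. **Descriptors** — GMRF window statistics (μ̃, Σ̃); a
   multisynchrosqueezing (MSST) spatial–temporal graph over six frequency
   bands built from the short-time periodogram `p(s,f) = |Y(s,f)|²/T`;
   an ambient sensor graph `R = (M, K)` with per-window activation
   features; thermal maps `TM = Σ ln(1 + Rᵢ)`; generalized-Gaussian
   (GGD) saliency `P(f) = θ/(2σΓ(θ⁻¹)) exp(−|f/σ|^θ)`; skeleton triangle
   angles `θ = atan2(‖u×v‖, u·v)`; and spider local image features on a
   polar web `x(n,m) = (m cos 2πn/N, m sin 2πn/N)`.
5. **Codebook** — one Gaussian mixture per family fitted by EM (k-means++
   init, ridge, monotone log-likelihood), soft-assignment histograms plus a
   Gaussian-mixture-regression generalized signal per window.
6. **Decoding** — an Elman RNN (`h_t = tanh(W_xh x_t + W_hh h_{t−1} + b)`)
   trained by backpropagation through time; accuracy, precision, recall and
   F1 from one-vs-rest confusion counts under 10-fold recording-level
   cross-validation.

A seeded synthetic-recording generator (activity-driven sinusoid bank IMU,
zone-based ambient events, rendered stick-figure frames, exact orientation
and skeleton ground truth) makes the whole pipeline testable offline.

## Worked example

```r
library(mmhar)

sc <- activity_script(
  data.frame(start_s = c(0, 6, 12, 18), end_s = c(6, 12, 18, 24),
             label = c("lying_down", "standing", "walking", "running")),
  sample_rate_imu = 50, fps_video = 8)
rec <- generate_recording(sc, seed = 1)
rec
#> <mm_recording> 24.0 s, 1200 IMU samples @ 50 Hz, 192 frames @ 8 fps, 17 ambient events

pre <- preprocess_imu(rec)
sel <- 701:900   # walking span, after the posture transition has settled
mean(vapply(sel, function(k)
  mmhar:::q_angle_between(pre$orient$q[k, ], rec$truth$orientation[k, ]),
  numeric(1))) * 180 / pi
#> [1] 1.38          # degrees of orientation error vs generator truth

vis <- preprocess_vision(rec)
skeleton_count(vis$skeletons[[70]])   # a standing frame
#> [1] 12            # all 12 landmarks recovered

feat <- extract_recording_features(rec, pipeline_config(seed = 1))
length(feat$labels); ncol(feat$families$motion_gmrf)
#> [1] 23            # 2-s windows at 50 % overlap over 24 s
#> [1] 27            # 6 channel means + 21 covariance entries
```

The full benchmark (20 recordings, 4 activities, 10-fold recording-level
cross-validation, per-fold codebook refits) runs in a few minutes on one
core:

```r
rep <- run_pipeline(pipeline_config(seed = 0))
rep
#> <eval_report> n=460 accuracy=0.9413 macro P/R/F1 = 0.9420/0.9412/0.9407
```

`0.9413` is the pooled fraction of correctly decoded 2-s windows; the
macro figures average one-vs-rest precision/recall/F1 over the four
activities. Reruns with the same seed are bit-identical.

A thin command-line wrapper is installed as `exec/hld`:

```sh
hld simulate --out /tmp/demo --seed 0 --recordings 2   # CSV/YAML recordings
hld run --seed 0 --out /tmp/report                     # full pipeline
```

## Package layout

- `R/synthetic-data.R` — seeded multimodal recording generator
- `R/imu-preprocess.R`, `R/dwt.R` — filtration chain and wavelet transform
- `R/vision-preprocess.R` — background model, masks, skeleton modelling
- `R/segmentation.R` — time windows and event segments
- `R/descriptors-*.R` — motion, ambient and vision descriptor families
- `R/codebook.R` — GMM-EM, GMR, segment encoding
- `R/classifier.R` — Elman RNN, metrics, cross-validation
- `R/pipeline.R` — end-to-end orchestration and ablation switches
- `vignettes/multimodal-locomotion-decoding.Rmd` — methods and design notes
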