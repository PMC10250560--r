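# dtuemp

Video-based quantification of **dual-task upper-extremity motor
performance (DTUEMP)**, and its use to assess cognitive and motor
function in older adults.

In the underlying protocol a participant repeatedly flexes and extends
the dominant elbow as fast as possible for 20 seconds while counting
backwards, filmed at 30 FPS. A pose network supplies per-frame elbow and
wrist keypoints; this package implements everything downstream of the
network, for researchers in movement analysis and digital biomarkers:

1. **Heatmap decoding** — joint coordinates from network score maps by
   the local-maximum method (`decode_heatmap()`).
2. **Lucas–Kanade optical flow** at the joints (`lk_flow()`), used to
   predict each keypoint's next-frame position.
3. **Coordinate correction** — the network track and the flow
   predictions are fused under the assumption that the two methods do
   not fail on the same joint in two consecutive frames: an isolated
   detector error (a keypoint blurred by fast motion) is replaced by the
   flow prediction chained from the last accepted coordinate
   (`correct_track()`).
4. **Kinematics** — the corrected track yields the rotation angle of the
   wrist–elbow line per frame (`compute_angle_sequence()`); local-peak
   segmentation marks each span from an angle minimum to the next
   maximum as a *flexion phase* and from a maximum to the next minimum
   as an *extension phase* (`segment_phases()`); the six DTUEMP metrics
   are the mean and SD of flexion, extension and flexion–extension
   (full-cycle) durations (`compute_metrics()`).
5. **Statistics** — Spearman and ICC(2,1) agreement against a
   sensor-derived reference with the conventional cut-offs, normality
   checks, the Blom rank-based inverse-normal transform, and partial
   correlation controlling age, sex and BMI (`spearman_assoc()`,
   `icc_agreement()`, `rank_inverse_normal()`, `partial_correlation()`).
6. **Outcome prediction** — an l1-regularised multi-task least-squares
   model fitted by monotone accelerated proximal gradient descent:

   minimise over W:  Σᵢ ‖XᵢWᵢ − Yᵢ‖²_F + ρ₁‖W‖₁ + ρ_L2‖W‖²_F

   with the z-scored DTUEMP metrics as predictors and MMSE (cognition,
   0–30 points) and TUG (mobility, seconds) as the two tasks
   (`mtl_lasso()`), a single-task Lasso benchmark (`stl_lasso()`), and
   five-fold cross-validated MAPE with nested penalty selection
   (`cv_mtl_lasso()`).

A synthetic-trial module (`trial_spec()`, `generate_trial()`,
`render_keypoints()`, `render_frames()`, `cohort_spec()`,
`generate_cohort()`) generates ground-truth trials, noisy keypoint
tracks with injected detector outliers, small rendered frame stacks for
the flow stage, and cohorts in which a shared sparse feature subset
drives both outcomes — so the full pipeline is testable without any
video recordings.

## Worked example

```r
library(dtuemp)

# a 20 s / 30 FPS trial with 5% isolated 80-px wrist detector outliers
spec    <- trial_spec(jitter_sd_px = 1, outlier_rate = 0.05,
                      outlier_magnitude_px = 80, seed = 42)
trial   <- generate_trial(spec)
network <- render_keypoints(trial)

# exact flow of the noise-free geometry stands in for Lucas-Kanade here
clean <- render_keypoints(generate_trial(
  trial_spec(jitter_sd_px = 0, outlier_rate = 0, seed = 42)))
res <- correct_track(network, displacement_flow(clean))
print(res$report)
#> Correction report: threshold 15.04 px, 600 frames
#>   elbow: 0 substituted frame(s)
#>   wrist: 27 substituted frame(s)

aN  <- compute_angle_sequence(network, variant = "network")
aC  <- compute_angle_sequence(res$track)
err <- angle_error_reduction(trial$theta_true, aN, aC)
#> RMSE uncorrected 15.94 deg, corrected 1.35 deg, reduction 91.5%

compute_metrics(segment_phases(aC))
#> DTUEMP metrics (seconds):
#>   flexion:           mean 1.063, SD 0.087  (n = 9)
#>   extension:         mean 1.056, SD 0.087  (n = 9)
#>   flexion-extension: mean 2.119, SD 0.171  (n = 9)
```

The corrected metrics match the generator's ground truth (flexion mean
1.059 s, cycle mean 2.119 s, cycle SD 0.171 s) to within one frame of
quantisation, while the 27 substituted frames are exactly the isolated
detector failures.

Outcome prediction on a synthetic cohort:

```r
co <- generate_cohort(cohort_spec(seed = 42))
cv_mtl_lasso(co, "mtl", seed = 42)
#> 5-fold cross-validation, MTL model (seed 42)
#>   mmse: MAPE 14.20% pooled (14.20% fold-mean) — moderate
#>   tug: MAPE 17.54% pooled (17.54% fold-mean) — moderate
```

On any single cohort either model can come out ahead (on this one the
single-task benchmark is marginally better for MMSE); the multi-task
advantage is a distributional claim, reproduced over 200 cohorts by the
acceptance script below.

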