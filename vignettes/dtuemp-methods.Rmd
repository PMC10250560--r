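---
title: "Methods: video-derived DTUEMP metrics and multi-task outcome prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: video-derived DTUEMP metrics and multi-task outcome prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtuemp)
```

# The measurement problem

Dual-task upper-extremity motor performance (DTUEMP) summarises a simple
bedside protocol: an older adult flexes and extends the dominant elbow
between full extension and full flexion as quickly as possible for 20
seconds while counting backwards, filmed at 30 FPS. Slower and more
variable movement under this cognitive load correlates with both
cognitive status (MMSE) and functional mobility (TUG), which makes the
six duration metrics — mean and SD of flexion-phase, extension-phase and
full-cycle durations — candidates for a camera-only screening signal
where wearable sensors are impractical.

A pose-estimation network supplies per-frame elbow and wrist pixel
coordinates. Everything in this package operates on that keypoint
stream; the network itself is a pluggable backend behind a keypoint CSV
contract, because the package's subject matter is what happens *after*
pose estimation: correcting isolated detector failures, converting
coordinates to an angle sequence, segmenting phases, and relating the
metrics to clinical scores.

# Coordinate correction

Pose networks fail in a characteristic way on this signal: the wrist
blurs during the fastest part of a stroke and the decoded coordinate
jumps far from the true joint for a single frame. Local optical flow
fails differently (drift, aperture problems), and the working assumption
is that the two estimators do not fail on the same joint in two
consecutive frames.

`correct_track()` therefore walks each joint independently. At frame
$t$ the Lucas–Kanade prediction is chained from the last *accepted*
coordinate, $\hat p_t = p^{acc}_{t-1} + f_{t-1}$. If the network
observation disagrees with $\hat p_t$ by more than a threshold and
frame $t-1$ was not itself a substitution, the flow prediction replaces
the network coordinate; otherwise — and always when the flow status is
not `ok` — the network observation is accepted.

Design choices worth stating:

* **Chaining from the accepted coordinate** means a *detected* error
  does not poison the next prediction. An *undetected* error (the
  forced network acceptance that ends a substitution run) does anchor
  the next prediction, and the run cap is the sole mechanism limiting
  trust in flow; both consequences are exercised in the tests.
* **Threshold**: default 0.25 of the median per-frame forearm length,
  making the rule invariant to image scale; an absolute-pixel mode
  exists for calibrated setups. An 80 px detector jump on a ~60 px
  forearm is far above this threshold, ordinary jitter far below.
* **Run cap** `max_consecutive_substitutions = 1` encodes the
  no-two-consecutive-failures assumption directly.
* Joints are corrected independently; nothing couples elbow and wrist
  errors.

# Optical flow

`lk_flow()` is the classic windowed least-squares estimator: central
difference spatial gradients, forward temporal difference, 2×2
structure-tensor solve over a 15 px window. Two numerical points:

* The solve is **iterated** (bilinear warp of the second frame by the
  current estimate, default cap 20, stop at 0.01 px updates), as
  practical Lucas–Kanade trackers do; a single linearised solve is only
  accurate for sub-pixel motion, while consecutive frames of this
  protocol move the wrist a few pixels.
* **Aperture failure** is declared when the structure tensor's least
  eigenvalue falls below 1e−6 or its condition number exceeds 1e6 —
  constant patches and pure edges cannot constrain both flow
  components, and the correction stage then simply trusts the network.

# Angle sequence and phase segmentation

The forearm angle is $\theta = \mathrm{atan2}(-(y_w - y_e),\; x_w -
x_e)$ in degrees: image y points down, so the sign flip makes
counterclockwise positive, with 0° a horizontal forearm pointing right.
The sequence is unwrapped so no step exceeds 180°. The duration metrics
depend only on *when* the angle peaks, so the angular reference is
immaterial to the outputs — which is also why duration metrics, not
angular amplitudes, are the deliverable.

Segmentation finds local maxima and minima with a prominence threshold
(default 10°, rejecting jitter-scale wiggles) and a minimum same-kind
separation (default 5 frames ≈ 0.17 s). Strict alternation is enforced
by keeping the most extreme of consecutive same-kind peaks (earliest on
ties). Minimum→maximum spans are flexion phases, maximum→minimum spans
extension phases; a cycle is a flexion phase plus the immediately
following extension phase, so each cycle duration is exactly the sum of
its two members.

**Endpoints.** Trials of this protocol begin and end at rest — at an
extreme of the movement. A sequence endpoint lying within 5% of the
signal range of the corresponding global extreme (and clearing the
prominence bar against the nearest interior peak) is therefore treated
as a genuine phase boundary. Without this rule the first and last phase
of every trial are discarded, and the SD metrics are computed over a
different phase subset than the ground truth, biasing them by several
hundredths of a second. A recording started mid-movement (e.g. a
sinusoid sampled from mid-range) leaves its endpoints mid-range, so the
rule does not fire and partial phases are dropped, as they should be.

Other conventions: sample SD (n−1 denominator) throughout; a phase kind
with fewer than two occurrences reports its mean and an `NA` SD; an
empty phase set yields all-`NA` metrics with a warning rather than an
error. No pre-smoothing is applied by default, so the metrics are
bit-reproducible from the corrected track; a 5-frame moving average is
available behind a config flag for rough inputs.

# Agreement and association statistics

The statistics battery mirrors standard method-comparison practice:

* **Spearman** — Pearson correlation of mid-ranks, p from the t
  approximation on n−2 df; labels weak < 0.35 ≤ moderate < 0.68 ≤
  strong.
* **ICC(2,1)** — two-way random effects, absolute agreement, single
  measures, computed from the two-way ANOVA mean squares. The
  absolute-agreement form is the right one for video-vs-sensor
  comparison because a systematic offset between measurement systems
  should count against agreement. Labels poor < 0.50 ≤ moderate < 0.75
  ≤ good < 0.90 ≤ excellent. The p-value is the F test of MSR/MSE.
* **Normality** — adjusted Fisher–Pearson skewness and excess kurtosis
  (the estimators mainstream statistical packages print, via `e1071`
  type 2), with a Shapiro–Wilk decision at 0.05.
* **Rank-based inverse normal** — Blom offset,
  $\Phi^{-1}\!\big((r - 3/8)/(n + 1/4)\big)$ with mid-ranks on ties.
* **Partial correlation** — residual-on-residual Pearson after
  regressing both variables on an intercept plus age, sex (0/1) and
  BMI; p from t on n−2−k df. A skewed outcome (TUG in practice) is
  passed through the inverse-normal transform first when it fails the
  Shapiro–Wilk gate; the metric side is left untransformed.

No multiple-testing correction is applied: per-metric inference at 0.05
replicates how such metric batteries are conventionally reported.

# The multi-task model

Both clinical outcomes are modelled jointly by
$$\min_W \sum_{i=1}^{t} \|X_i W_i - Y_i\|_F^2 + \rho_1 \|W\|_1
  + \rho_{L2} \|W\|_F^2,$$
with the z-scored six metrics as predictors and outcomes centred per
task (intercepts are the task means). With the element-wise $\ell_1$
penalty the objective decouples across tasks *for a fixed penalty*; the
multi-task coupling is that a single $\rho_1$ is selected once for all
tasks by cross-validation on the across-task mean error, whereas the
single-task benchmark tunes each outcome independently. At cohort sizes
of a few dozen, hyperparameter selection is the variance-dominated step,
and averaging the selection criterion across related tasks is precisely
where sharing statistical strength pays.

Solver: monotone FISTA (accelerated proximal gradient with rejection of
non-improving steps and momentum restart), soft-thresholding prox for
the $\ell_1$ term, ridge folded into the smooth part, step size $1/L$
with $L = 2\max_i \lambda_{max}(X_i^\top X_i) + 2\rho_{L2}$.
Initialisation at $W = 0$. Convergence is declared on the **subgradient
(KKT) residual** falling below 1e−6 rather than on objective change: an
objective-change rule fires while coefficients can still be off by ~1e−4
(the objective is flat near the optimum), which matters when the fit is
compared against closed forms. A rejected momentum-free step — a plain
proximal-gradient step that fails to improve the objective — marks
machine-precision stationarity and also terminates. The objective trace
is non-increasing by construction; non-convergence warns and flags,
never passes silently.

Cross-validation (`cv_mtl_lasso()`): seeded shuffled 5-fold outer
partition, identical folds for both model kinds at the same seed.
Within each training fold, predictors are z-scored on that fold only
(no leakage; perturbing test-fold outcomes provably leaves their
predictions unchanged, and a test asserts this) and $\rho_1$ is chosen
by inner 3-fold search on a 7-point logarithmic grid
$\{10^{-3} \dots 10^{0}\}\cdot\rho_1^{max}$ anchored at the fold's
critical penalty. The grid tops out at $\rho_1^{max}$ because every
penalty at or above it provably yields $W = 0$; points beyond would
duplicate the null model, and the null model stays selectable at the
top of the grid. MAPE is reported pooled over all out-of-fold
predictions (primary) and as the mean of per-fold MAPEs; the
single-task benchmark shares the same grid, folds and seed, and differs
only in per-task selection.

# What the synthetic generator emulates — and what it does not

`generate_trial()` produces a triangular wave: linear flexion ramps
(minimum to maximum angle) and extension ramps back, with per-cycle
periods drawn from a normal distribution (default mean 2 s, SD 0.2 s)
truncated at 0.2 s and quantised to whole frames, so that every phase
boundary is exactly known. The defaults encode the protocol constants
(20 s, 30 FPS) and a plausible movement range (0–120°, ~60 px forearm).
The real distribution of cycle-time variability in the clinical
population is unknown; these are working values for testing machinery,
not population estimates.

`render_keypoints()` adds isotropic Gaussian jitter (default 1 px) and,
with a per-frame probability (never in two consecutive frames for the
same joint, matching the correction assumption), displaces the wrist by
a fixed magnitude in a random direction — the isolated single-frame
detector failure mode. The image y-axis points down and the renderer
uses $-\sin\theta$ so increasing angle moves the wrist up on screen.
Outliers target the wrist by default because the fast-moving distal
joint is where real detectors blur; both joints can be targeted.

`generate_cohort()` draws standard-normal features, picks a sparse
support (default 3 of 6) shared by both outcomes, and builds MMSE
negatively and TUG positively on that support with task-specific
magnitudes, Gaussian noise, and covariates matched to the intended
clinical population (age 78.15 ± 6.48, 60% female, BMI 25.18 ± 4.07,
offsets MMSE 25.75 and TUG 11.42 s). Noise SDs (2.5 MMSE points, 1.5 s
TUG) were set so that simulated outcome spreads resemble that
population's. MMSE is clipped to [0, 30] and TUG floored at 3 s, with
clipping events recorded.

What passing tests on these fixtures show: the pipeline's algebra,
segmentation, correction logic, statistics and solver are correct, and
the multi-task-beats-single-task ordering emerges under shared sparse
support. What they do not show: performance under real pose-network
error structure (correlated, pose-dependent, not isolated), soft-tissue
artefact, camera motion, or real clinical covariance between metrics
and outcomes. Triangular ramps also make peak detection easier than
smooth human kinematics near turnarounds; the sinusoid tests partially
cover that gap.

# Degenerate inputs and edge behaviour

* Flat heatmaps decode to (0, 0) with confidence 0 and a warning;
  argmax ties break at the smallest row-major index, bit-exactly.
* Coincident wrist and elbow make the angle undefined: error naming the
  frame.
* Monotone angle sequences have no interior peaks: empty phase set
  (message, not an error), all-`NA` metrics with a warning.
* Constant or edge-only flow windows: `aperture_failure`; windows
  crossing the frame border: `out_of_bounds`; both fall back to the
  network coordinate in correction.
* Zero-variance predictors abort fitting with the feature named; zero
  observed outcomes abort MAPE (MMSE and TUG are positive by scale).
* All generators, the cross-validation and the pipeline are pure
  functions of their seed: identical inputs produce byte-identical
  outputs, asserted in the tests.

# Problem sizes

The test-suite and acceptance-script simulations use 20-second,
600-frame trials; 100 seeded trials for the correction and flow
studies; 20 solver problems at n = 16, p = 6, t = 2 against a
coordinate-descent oracle run to 1e−14; and 200 cohorts of n = 20 for
the multi-task versus single-task comparison. These sizes put every
Monte-Carlo bound comfortably inside its sampling error while keeping
the whole suite runnable on one CPU in a few minutes.

# Known limitations

* The pose network itself is out of scope; real-world accuracy is
  bounded by the backend feeding the keypoint CSV.
* The correction rule handles isolated failures only; two consecutive
  detector errors on a joint defeat it by assumption, and the frame
  after a forced acceptance can be substituted from a corrupt anchor.
* Single-level Lucas–Kanade limits trackable motion to roughly the
  window radius per frame; no pyramid is implemented.
* Duration metrics ignore amplitude and smoothness information that a
  richer kinematic analysis would use.
* The multi-task formulation couples tasks only through shared penalty
  selection; structured penalties (group or trace norms) that couple
  weights directly are deliberately out of scope.
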