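#' Specify a synthetic elbow flexion-extension trial
#'
#' Builds the parameter object for [generate_trial()]. Defaults emulate the
#' standard dual-task protocol: a 20-second trial filmed at 30 FPS in which
#' the participant repeatedly flexes and extends the elbow between full
#' extension and full flexion as quickly as possible. The true angle is a
#' triangular wave: linear ramps from the minimum to the maximum angle
#' (flexion) and back (extension), with per-cycle periods drawn from a
#' normal distribution so that phase durations vary between cycles exactly
#' as recorded in the ground truth.
#'
#' @param duration_s trial length in seconds (> 0).
#' @param fps frame rate in Hz (> 0).
#' @param elbow_anchor numeric length-2, pixel position (x, y) of the elbow.
#' @param forearm_len forearm length in pixels (> 0); wrist-elbow distance.
#' @param cycle_period_mean_s mean flexion-extension cycle period, seconds.
#' @param cycle_period_sd_s SD of the cycle period across cycles, seconds.
#' @param angle_min_deg,angle_max_deg angular range of the forearm in
#'   degrees (`angle_max_deg > angle_min_deg`). 0 deg is a horizontal
#'   forearm pointing right; +90 deg points up on screen.
#' @param jitter_sd_px SD of isotropic Gaussian keypoint jitter, pixels.
#' @param outlier_rate per-frame probability of an isolated detector
#'   outlier, in \[0, 0.5).
#' @param outlier_magnitude_px displacement of an outlying observation,
#'   pixels.
#' @param outlier_joints joints subject to outlier injection; fast-moving
#'   distal joints are the usual failure mode, so the default is the wrist.
#' @param seed integer seed; all generation is deterministic given the spec.
#' @return An object of class `"trial_spec"`.
#' @seealso [generate_trial()], [render_keypoints()], [render_frames()]
#' @export
#' @examples
#' spec <- trial_spec(cycle_period_sd_s = 0, seed = 1)
#' trial <- generate_trial(spec)
#' range(trial$theta_true)
trial_spec <- function(duration_s = 20, fps = 30,
                       elbow_anchor = c(160, 120), forearm_len = 60,
                       cycle_period_mean_s = 2, cycle_period_sd_s = 0.2,
                       angle_min_deg = 0, angle_max_deg = 120,
                       jitter_sd_px = 1, outlier_rate = 0,
                       outlier_magnitude_px = 80,
                       outlier_joints = "wrist", seed = 1L) {
  check_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  check_number(fps, "fps", lower = 0, strict_lower = TRUE)
  check_number(forearm_len, "forearm_len", lower = 0, strict_lower = TRUE)
  check_number(cycle_period_mean_s, "cycle_period_mean_s",
               lower = 0, strict_lower = TRUE)
  check_number(cycle_period_sd_s, "cycle_period_sd_s", lower = 0)
  check_number(angle_min_deg, "angle_min_deg")
  check_number(angle_max_deg, "angle_max_deg")
  if (angle_max_deg <= angle_min_deg) {
    stop_dtuemp("'angle_max_deg' must exceed 'angle_min_deg'")
  }
  check_number(jitter_sd_px, "jitter_sd_px", lower = 0)
  check_number(outlier_rate, "outlier_rate", lower = 0, upper = 0.5,
               strict_upper = TRUE)
  check_number(outlier_magnitude_px, "outlier_magnitude_px", lower = 0)
  if (!is.numeric(elbow_anchor) || length(elbow_anchor) != 2L ||
      any(!is.finite(elbow_anchor))) {
    stop_dtuemp("'elbow_anchor' must be a finite (x, y) pair")
  }
  outlier_joints <- match.arg(outlier_joints, c("wrist", "elbow", "both"),
                              several.ok = FALSE)
  structure(list(
    duration_s = duration_s, fps = fps,
    elbow_anchor = as.numeric(elbow_anchor), forearm_len = forearm_len,
    cycle_period_mean_s = cycle_period_mean_s,
    cycle_period_sd_s = cycle_period_sd_s,
    angle_min_deg = angle_min_deg, angle_max_deg = angle_max_deg,
    jitter_sd_px = jitter_sd_px, outlier_rate = outlier_rate,
    outlier_magnitude_px = outlier_magnitude_px,
    outlier_joints = outlier_joints, seed = as.integer(seed)
  ), class = "trial_spec")
}

# Draw one cycle period, redrawing (up to 100 times) while it falls at or
# below the 0.2-second floor.
draw_period <- function(mean_s, sd_s) {
  for (i in seq_len(100L)) {
    p <- stats::rnorm(1L, mean_s, sd_s)
    if (p > 0.2) return(p)
  }
  stop_dtuemp(paste(
    "could not draw a cycle period above 0.2 s in 100 attempts;",
    "check cycle_period_mean_s/cycle_period_sd_s"))
}

#' Generate a ground-truth flexion-extension trial
#'
#' Produces the true wrist-elbow angle sequence and the exact phase
#' boundaries of a synthetic trial. The angle is a triangular wave whose
#' cycle periods are drawn from
#' `Normal(cycle_period_mean_s, cycle_period_sd_s)` truncated at 0.2 s;
#' each cycle is split into a flexion ramp (minimum to maximum angle) and
#' an extension ramp (maximum to minimum), each quantised to a whole number
#' of frames so that the recorded phase boundaries are exact.
#'
#' Frames are indexed from 0. A phase ending at the final boundary
#' `n_frames` ends at the trial's closing instant, which is not itself a
#' sampled frame.
#'
#' @param spec a [trial_spec()] object.
#' @return An object of class `"gt_trial"`: a list with `theta_true`
#'   (degrees per frame, length `round(duration_s * fps)`), `phase_truth`
#'   (data frame of `kind`, `start_frame`, `end_frame`, `duration_s` for
#'   every complete phase), `cycle_periods_s` (the realised per-cycle
#'   durations after frame quantisation), `n_frames`, `fps` and `spec`.
#' @export
generate_trial <- function(spec) {
  stopifnot(inherits(spec, "trial_spec"))
  n_frames <- round(spec$duration_s * spec$fps)
  if (n_frames < 2L) stop_dtuemp("trial must span at least 2 frames")

  with_seed(spec$seed, {
    verts <- 0L          # vertex frame indices, starting at angle_min
    kinds <- character(0)
    v <- 0L
    while (v < n_frames) {
      p <- draw_period(spec$cycle_period_mean_s, spec$cycle_period_sd_s)
      cyc <- max(2L, as.integer(round(p * spec$fps)))
      flex <- max(1L, as.integer(round(cyc / 2)))
      ext <- max(1L, cyc - flex)
      verts <- c(verts, v + flex, v + flex + ext)
      kinds <- c(kinds, "flexion", "extension")
      v <- v + flex + ext
    }
    verts
  }) -> verts_holder
  verts <- verts_holder

  # Piecewise-linear angle between alternating min/max vertices.
  n_vert <- length(verts)
  vert_angle <- rep(c(spec$angle_min_deg, spec$angle_max_deg),
                    length.out = n_vert)
  theta_true <- stats::approx(x = verts, y = vert_angle,
                              xout = seq_len(n_frames) - 1L)$y

  kinds <- rep(c("flexion", "extension"), length.out = n_vert - 1L)
  starts <- verts[-n_vert]
  ends <- verts[-1L]
  keep <- ends <= n_frames
  phase_truth <- data.frame(
    kind = kinds[keep],
    start_frame = starts[keep],
    end_frame = ends[keep],
    duration_s = (ends[keep] - starts[keep]) / spec$fps,
    stringsAsFactors = FALSE
  )

  flex_idx <- which(phase_truth$kind == "flexion")
  cycle_periods <- numeric(0)
  for (i in flex_idx) {
    if (i + 1L <= nrow(phase_truth)) {
      cycle_periods <- c(cycle_periods,
                         phase_truth$duration_s[i] +
                           phase_truth$duration_s[i + 1L])
    }
  }

  structure(list(
    theta_true = theta_true,
    phase_truth = phase_truth,
    cycle_periods_s = cycle_periods,
    n_frames = n_frames,
    fps = spec$fps,
    spec = spec
  ), class = "gt_trial")
}

#' @export
print.gt_trial <- function(x, ...) {
  cat(sprintf(
    "Ground-truth trial: %d frames @ %g fps (%.1f s), %d phases, %d cycles\n",
    x$n_frames, x$fps, x$n_frames / x$fps, nrow(x$phase_truth),
    length(x$cycle_periods_s)))
  cat(sprintf("  angle range: %g to %g deg\n",
              x$spec$angle_min_deg, x$spec$angle_max_deg))
  invisible(x)
}

new_trial_track <- function(data, fps, source = "synthetic") {
  stopifnot(is.data.frame(data), fps > 0)
  need <- c("frame", "elbow_x", "elbow_y", "wrist_x", "wrist_y")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop_dtuemp("track missing columns: %s",
                                paste(miss, collapse = ", "))
  structure(list(data = data, fps = fps, n_frames = nrow(data),
                 source = source), class = "trial_track")
}

#' @export
print.trial_track <- function(x, ...) {
  n_out <- sum(x$data$wrist_outlier %||% FALSE) +
    sum(x$data$elbow_outlier %||% FALSE)
  cat(sprintf("Trial track (%s): %d frames @ %g fps, %d flagged outliers\n",
              x$source, x$n_frames, x$fps, n_out))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render noisy keypoint observations from a ground-truth trial
#'
#' Turns the true angle sequence into per-frame elbow and wrist pixel
#' observations the way a pose network would see them: the elbow sits at
#' its anchor, the wrist at `forearm_len` pixels along the forearm
#' direction (image y axis points down, so increasing angle moves the
#' wrist up on screen), and both joints receive isotropic Gaussian jitter.
#' With probability `outlier_rate` per frame an isolated detector failure
#' displaces the observed joint by `outlier_magnitude_px` in a uniformly
#' random direction; injection is suppressed in the frame immediately
#' after an outlier of the same joint, so injected outliers are never
#' consecutive — the assumption the downstream correction algorithm relies
#' on. Outlier frames are flagged in the track.
#'
#' @param trial a [generate_trial()] result.
#' @param seed integer seed for jitter and outliers; defaults to
#'   `spec$seed + 1` so that trial-shape and observation noise use
#'   distinct streams.
#' @return A `"trial_track"` object whose `data` holds per-frame
#'   `elbow_x/y`, `wrist_x/y`, confidences and per-joint outlier flags.
#' @export
render_keypoints <- function(trial, seed = trial$spec$seed + 1L) {
  stopifnot(inherits(trial, "gt_trial"))
  spec <- trial$spec
  n <- trial$n_frames
  th <- trial$theta_true * pi / 180

  with_seed(seed, {
    ex <- spec$elbow_anchor[1] + stats::rnorm(n, 0, spec$jitter_sd_px)
    ey <- spec$elbow_anchor[2] + stats::rnorm(n, 0, spec$jitter_sd_px)
    wx <- spec$elbow_anchor[1] + spec$forearm_len * cos(th) +
      stats::rnorm(n, 0, spec$jitter_sd_px)
    wy <- spec$elbow_anchor[2] - spec$forearm_len * sin(th) +
      stats::rnorm(n, 0, spec$jitter_sd_px)

    inject <- function(x, y) {
      out <- logical(n)
      for (t in seq_len(n)) {
        if (t > 1L && out[t - 1L]) next  # rejection: never consecutive
        if (stats::runif(1L) < spec$outlier_rate) {
          ang <- stats::runif(1L, 0, 2 * pi)
          x[t] <- x[t] + spec$outlier_magnitude_px * cos(ang)
          y[t] <- y[t] + spec$outlier_magnitude_px * sin(ang)
          out[t] <- TRUE
        }
      }
      list(x = x, y = y, out = out)
    }

    wrist_out <- logical(n)
    elbow_out <- logical(n)
    if (spec$outlier_rate > 0) {
      if (spec$outlier_joints %in% c("wrist", "both")) {
        r <- inject(wx, wy); wx <- r$x; wy <- r$y; wrist_out <- r$out
      }
      if (spec$outlier_joints %in% c("elbow", "both")) {
        r <- inject(ex, ey); ex <- r$x; ey <- r$y; elbow_out <- r$out
      }
    }

    data.frame(
      frame = seq_len(n) - 1L,
      elbow_x = ex, elbow_y = ey, wrist_x = wx, wrist_y = wy,
      elbow_confidence = 1, wrist_confidence = 1,
      elbow_outlier = elbow_out, wrist_outlier = wrist_out
    )
  }) -> dat

  new_trial_track(dat, fps = spec$fps, source = "synthetic")
}

# Separable Gaussian smoothing with replicated edges (small kernels only).
smooth2d <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv <- function(v) {
    vp <- c(rep(v[1], r), v, rep(v[length(v)], r))
    stats::filter(vp, k, sides = 2)[(r + 1):(r + length(v))]
  }
  m <- apply(m, 2L, pad_conv)
  t(apply(m, 1L, pad_conv))
}

#' Render grayscale test frames from a keypoint track
#'
#' Produces a stack of small grayscale images: a fixed seeded background
#' texture (smoothed noise, shared by all frames) plus a Gaussian blob at
#' the elbow and at the wrist coordinate of each frame. The frames exist
#' to exercise the optical-flow stage, not to look like video of a person.
#'
#' Pixel coordinates are zero-based with x as column and y as row; the
#' intensity of pixel (x, y) in frame `f` is `frames[[f]][y + 1, x + 1]`.
#'
#' @param track a `"trial_track"`.
#' @param size frame side length in pixels (>= 48).
#' @param blob_sigma blob radius parameter in pixels.
#' @param blob_amplitude peak blob intensity over the background.
#' @param background_amplitude amplitude of the background texture.
#' @param seed seed for the background texture.
#' @return A list of `size` x `size` numeric matrices, one per frame.
#' @export
render_frames <- function(track, size = 64, blob_sigma = 2,
                          blob_amplitude = 1, background_amplitude = 0.15,
                          seed = 99L) {
  stopifnot(inherits(track, "trial_track"))
  if (size < 48) stop_dtuemp("'size' must be at least 48 px")
  d <- track$data
  bad <- which(d$elbow_x < 0 | d$elbow_x > size - 1 |
                 d$elbow_y < 0 | d$elbow_y > size - 1 |
                 d$wrist_x < 0 | d$wrist_x > size - 1 |
                 d$wrist_y < 0 | d$wrist_y > size - 1)
  if (length(bad)) {
    stop_dtuemp("keypoints outside %dx%d frame bounds at frame %d",
                size, size, d$frame[bad[1]])
  }
  bg <- with_seed(seed, {
    m <- matrix(stats::runif(size * size), size, size)
    m <- smooth2d(m, sigma = 1.5)
    background_amplitude * (m - min(m)) / (max(m) - min(m))
  })
  xs <- matrix(rep(0:(size - 1), each = size), size, size)   # col index
  ys <- matrix(rep(0:(size - 1), times = size), size, size)  # row index
  blob <- function(cx, cy) {
    blob_amplitude * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * blob_sigma^2))
  }
  lapply(seq_len(nrow(d)), function(i) {
    bg + blob(d$elbow_x[i], d$elbow_y[i]) + blob(d$wrist_x[i], d$wrist_y[i])
  })
}

#' Specify a synthetic cohort for outcome regression
#'
#' Parameters of [generate_cohort()]. Defaults mirror the demographics of
#' the intended clinical population: about twenty older adults, age
#' 78 +/- 6.5 years, 60% female, BMI 25 +/- 4, MMSE centred near 25.75
#' and TUG near 11.42 s. Both outcomes are driven by the same sparse
#' subset of the six DTUEMP features with task-specific magnitudes:
#' slower, more variable movement lowers MMSE and raises TUG, so the
#' shared support enters the MMSE model negatively and the TUG model
#' positively.
#'
#' @param n_subjects cohort size (>= 10).
#' @param n_features number of DTUEMP predictors (default 6: mean and SD
#'   of flexion, extension and flexion-extension phase).
#' @param support_size number of active features shared by both tasks.
#' @param weight_scale multiplies both tasks' weight magnitudes.
#' @param noise_sd length-2 (MMSE points, TUG seconds) outcome noise SDs.
#' @param outcome_offsets length-2 intercepts (MMSE points, TUG seconds).
#' @param age_mean,age_sd,sex_prob,bmi_mean,bmi_sd covariate distributions;
#'   sex is coded 1 = female with probability `sex_prob`.
#' @param seed integer seed.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_subjects = 20, n_features = 6, support_size = 3,
                        weight_scale = 1, noise_sd = c(2.5, 1.5),
                        outcome_offsets = c(25.75, 11.42),
                        age_mean = 78.15, age_sd = 6.48, sex_prob = 0.6,
                        bmi_mean = 25.18, bmi_sd = 4.07, seed = 1L) {
  check_number(n_subjects, "n_subjects", lower = 10)
  check_number(n_features, "n_features", lower = 1)
  check_number(support_size, "support_size", lower = 1)
  if (support_size > n_features) {
    stop_dtuemp("'support_size' cannot exceed 'n_features'")
  }
  if (length(noise_sd) != 2L || any(noise_sd < 0)) {
    stop_dtuemp("'noise_sd' must be two non-negative values (MMSE, TUG)")
  }
  if (length(outcome_offsets) != 2L) {
    stop_dtuemp("'outcome_offsets' must be length 2 (MMSE, TUG)")
  }
  structure(list(
    n_subjects = as.integer(n_subjects), n_features = as.integer(n_features),
    support_size = as.integer(support_size), weight_scale = weight_scale,
    noise_sd = as.numeric(noise_sd),
    outcome_offsets = as.numeric(outcome_offsets),
    age_mean = age_mean, age_sd = age_sd, sex_prob = sex_prob,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Generate a synthetic cohort table
#'
#' Draws standard-normal DTUEMP features, selects a sparse support shared
#' by both outcomes, and builds MMSE and TUG as linear responses with
#' task-specific weight magnitudes on that support plus Gaussian noise.
#' MMSE decreases and TUG increases with the active features. MMSE is
#' clipped to its 0-30 scale and TUG floored at 3 s; any clipping is
#' recorded in the `clipped` attribute.
#'
#' @param spec a [cohort_spec()] object.
#' @return A data frame of class `"cohort_table"` with columns `subject`,
#'   `metric_1..metric_p`, `age`, `sex`, `bmi`, `mmse`, `tug`. The true
#'   weights and support are attached as attributes `support`, `w_mmse`,
#'   `w_tug`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  p <- spec$n_features
  with_seed(spec$seed, {
    X <- matrix(stats::rnorm(n * p), n, p)
    support <- sort(sample.int(p, spec$support_size))
    w_m <- numeric(p)
    w_t <- numeric(p)
    w_m[support] <- spec$weight_scale * stats::runif(spec$support_size, 1.5, 3.5)
    w_t[support] <- spec$weight_scale * stats::runif(spec$support_size, 1.2, 2.6)
    mmse_raw <- spec$outcome_offsets[1] - drop(X %*% w_m) +
      stats::rnorm(n, 0, spec$noise_sd[1])
    tug_raw <- spec$outcome_offsets[2] + drop(X %*% w_t) +
      stats::rnorm(n, 0, spec$noise_sd[2])
    age <- stats::rnorm(n, spec$age_mean, spec$age_sd)
    sex <- stats::rbinom(n, 1L, spec$sex_prob)
    bmi <- stats::rnorm(n, spec$bmi_mean, spec$bmi_sd)
    list(X = X, support = support, w_m = w_m, w_t = w_t,
         mmse_raw = mmse_raw, tug_raw = tug_raw,
         age = age, sex = sex, bmi = bmi)
  }) -> g

  mmse <- pmin(30, pmax(0, g$mmse_raw))
  tug <- pmax(3, g$tug_raw)
  clipped <- data.frame(
    outcome = c(rep("mmse", sum(mmse != g$mmse_raw)),
                rep("tug", sum(tug != g$tug_raw))),
    subject = c(which(mmse != g$mmse_raw), which(tug != g$tug_raw))
  )

  out <- data.frame(subject = seq_len(n), g$X, age = g$age, sex = g$sex,
                    bmi = g$bmi, mmse = mmse, tug = tug)
  names(out)[2:(1 + p)] <- paste0("metric_", seq_len(p))
  attr(out, "support") <- g$support
  attr(out, "w_mmse") <- g$w_m
  attr(out, "w_tug") <- g$w_t
  attr(out, "clipped") <- clipped
  class(out) <- c("cohort_table", "data.frame")
  out
}
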