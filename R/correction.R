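#' Correction settings for network/flow track fusion
#'
#' @param disagreement_threshold positive disagreement threshold. With
#'   `threshold_mode = "relative"` (default) it is a fraction of the
#'   median per-frame forearm length (scale-invariant); with
#'   `"absolute"` it is in pixels.
#' @param threshold_mode `"relative"` or `"absolute"`.
#' @param max_consecutive_substitutions longest permitted run of flow
#'   substitutions per joint. The default 1 encodes the working
#'   assumption that detector and flow errors never coincide in two
#'   consecutive frames, so a single flow step is always anchored to a
#'   trusted coordinate.
#' @return An object of class `"correction_config"`.
#' @export
correction_config <- function(disagreement_threshold = 0.25,
                              threshold_mode = c("relative", "absolute"),
                              max_consecutive_substitutions = 1L) {
  threshold_mode <- match.arg(threshold_mode)
  check_number(disagreement_threshold, "disagreement_threshold",
               lower = 0, strict_lower = TRUE)
  check_number(max_consecutive_substitutions,
               "max_consecutive_substitutions", lower = 1)
  structure(list(disagreement_threshold = disagreement_threshold,
                 threshold_mode = threshold_mode,
                 max_consecutive_substitutions =
                   as.integer(max_consecutive_substitutions)),
            class = "correction_config")
}

#' Correct a network keypoint track with optical-flow predictions
#'
#' Fuses the pose-network track with Lucas-Kanade flow into a corrected
#' track. Each joint is treated independently. At every frame t >= 1 the
#' flow prediction is chained from the last accepted coordinate:
#' `p_hat = accepted(t-1) + flow(t-1)`. When the network observation
#' disagrees with `p_hat` by more than the threshold — and the previous
#' frame was not itself a substitution (capping substitution runs, by
#' default at one frame) — the flow prediction replaces the network
#' coordinate. Otherwise, and always when the flow failed (aperture
#' failure or out of bounds), the network coordinate is accepted. Frame 0
#' is always the network observation.
#'
#' Chaining from the accepted coordinate (rather than the raw network
#' coordinate of the previous frame) means a detected detector error does
#' not poison the next frame's prediction; the run cap means flow is
#' never trusted for long stretches, since local flow drifts.
#'
#' @param network a `"trial_track"` of network observations.
#' @param flow flow data frame (from [track_flow()] or
#'   [displacement_flow()]) covering frames 0..n-2 for both joints.
#' @param config a [correction_config()].
#' @return A list with `track` (the corrected `"trial_track"`, source
#'   `"corrected"`) and `report` (class `"correction_report"`: per-joint
#'   substituted frame indices and per-frame disagreement in pixels).
#' @export
correct_track <- function(network, flow, config = correction_config()) {
  stopifnot(inherits(network, "trial_track"))
  if (!inherits(config, "correction_config")) {
    stop_dtuemp("'config' must be a correction_config()")
  }
  d <- network$data
  n <- network$n_frames

  threshold_px <- config$disagreement_threshold
  if (config$threshold_mode == "relative") {
    forearm <- sqrt((d$wrist_x - d$elbow_x)^2 + (d$wrist_y - d$elbow_y)^2)
    threshold_px <- config$disagreement_threshold * stats::median(forearm)
  }

  out <- d
  report <- list()
  for (j in c("elbow", "wrist")) {
    fj <- flow[flow$joint == j, , drop = FALSE]
    fj <- fj[order(fj$frame), , drop = FALSE]
    if (nrow(fj) < n - 1L) {
      stop_dtuemp("flow for joint '%s' covers %d frame pairs; need %d",
                  j, nrow(fj), n - 1L)
    }
    xs <- d[[paste0(j, "_x")]]
    ys <- d[[paste0(j, "_y")]]
    acc_x <- xs
    acc_y <- ys
    substituted <- logical(n)
    disagreement <- rep(NA_real_, n)
    run_len <- 0L
    for (t in 2:n) {
      ft <- fj[t - 1L, ]
      if (!identical(ft$status, "ok")) {
        run_len <- 0L
        next  # no usable flow: accept network
      }
      px <- acc_x[t - 1L] + ft$u
      py <- acc_y[t - 1L] + ft$v
      disagreement[t] <- sqrt((xs[t] - px)^2 + (ys[t] - py)^2)
      if (disagreement[t] > threshold_px &&
          run_len < config$max_consecutive_substitutions) {
        acc_x[t] <- px
        acc_y[t] <- py
        substituted[t] <- TRUE
        run_len <- run_len + 1L
      } else {
        run_len <- 0L
      }
    }
    out[[paste0(j, "_x")]] <- acc_x
    out[[paste0(j, "_y")]] <- acc_y
    report[[j]] <- list(substituted_frames = d$frame[substituted],
                        disagreement_px = disagreement)
  }

  report$threshold_px <- threshold_px
  report$n_frames <- n
  class(report) <- "correction_report"
  list(track = new_trial_track(out, fps = network$fps, source = "corrected"),
       report = report)
}

#' @export
print.correction_report <- function(x, ...) {
  cat(sprintf("Correction report: threshold %.2f px, %d frames\n",
              x$threshold_px, x$n_frames))
  for (j in c("elbow", "wrist")) {
    cat(sprintf("  %s: %d substituted frame(s)\n", j,
                length(x[[j]]$substituted_frames)))
  }
  invisible(x)
}

#' Angle-accuracy gain from coordinate correction
#'
#' Frame-wise RMSE, in degrees, of an uncorrected and a corrected angle
#' sequence against the ground truth, and the relative reduction
#' `1 - RMSE_corrected / RMSE_uncorrected`.
#'
#' @param truth,uncorrected,corrected numeric angle sequences (degrees) of
#'   equal length, or `"angle_sequence"` objects.
#' @return A list with `rmse_uncorrected`, `rmse_corrected` (degrees) and
#'   `reduction` (fraction; 1 means the corrected sequence matches truth).
#' @export
angle_error_reduction <- function(truth, uncorrected, corrected) {
  truth <- as_angle_values(truth)
  uncorrected <- as_angle_values(uncorrected)
  corrected <- as_angle_values(corrected)
  n <- length(truth)
  if (n == 0L) stop_dtuemp("angle sequences must be non-empty")
  if (length(uncorrected) != n || length(corrected) != n) {
    stop_dtuemp("angle sequences must have equal length")
  }
  rmse <- function(a) sqrt(mean((a - truth)^2))
  ru <- rmse(uncorrected)
  rc <- rmse(corrected)
  list(rmse_uncorrected = ru, rmse_corrected = rc,
       reduction = if (ru == 0) 0 else 1 - rc / ru)
}

as_angle_values <- function(a) {
  if (inherits(a, "angle_sequence")) a$values else as.numeric(a)
}
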