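#' Lucas-Kanade optical flow at a point
#'
#' Estimates the displacement of a point between two consecutive grayscale
#' frames by the classic local least-squares method: over a square window
#' centred on the point, spatial gradients (central differences) and the
#' temporal difference (frame 2 minus frame 1) are combined in the 2x2
#' normal equations `G (u, v)' = b`, where `G` is the structure tensor.
#' As in practical Lucas-Kanade trackers, the solve is iterated: after
#' each solve the second frame is re-sampled (bilinearly) at the window
#' displaced by the current estimate and the residual re-solved, until
#' the update falls below 0.01 px or `iterations` is reached. One
#' iteration recovers only sub-pixel motion accurately; the default
#' budget handles the few-pixel inter-frame motions of a 30-FPS trial.
#' The solve fails with `status = "aperture_failure"` when the window's
#' texture does not constrain both motion components: the structure
#' tensor's condition number exceeds 1e6 or its least eigenvalue falls
#' below 1e-6. Points whose window (plus the one-pixel gradient margin)
#' does not fit inside the frames return `status = "out_of_bounds"`.
#'
#' Frames must be single-channel numeric matrices of equal size;
#' multi-channel arrays are averaged to luminance first. The estimator is
#' single-level (no pyramid): it is accurate for sub-window motions, the
#' regime of consecutive 30-FPS frames of an elbow flexion-extension
#' trial.
#'
#' @param frame_t,frame_t1 grayscale frames at times t and t+1.
#' @param point numeric (x, y), zero-based pixel coordinate of the point
#'   in `frame_t`.
#' @param window_px odd window side length in pixels (default 15).
#' @param iterations maximum Newton refinement steps (default 20).
#' @param joint optional joint label carried through to the result.
#' @param frame_index optional zero-based frame index of `frame_t`.
#' @return A one-row data frame with `u`, `v` (pixels/frame), `joint`,
#'   `frame`, `status` (`"ok"`, `"aperture_failure"` or
#'   `"out_of_bounds"`).
#' @export
lk_flow <- function(frame_t, frame_t1, point, window_px = 15L,
                    iterations = 20L,
                    joint = NA_character_, frame_index = NA_integer_) {
  frame_t <- as_gray(frame_t)
  frame_t1 <- as_gray(frame_t1)
  if (!all(dim(frame_t) == dim(frame_t1))) {
    stop_dtuemp("frames must have identical dimensions")
  }
  if (window_px %% 2 != 1 || window_px < 3) {
    stop_dtuemp("'window_px' must be an odd integer >= 3")
  }
  if (length(point) != 2L || any(!is.finite(point))) {
    stop_dtuemp("'point' must be a finite (x, y) pair")
  }

  res <- function(u, v, status) {
    data.frame(u = u, v = v, joint = joint, frame = frame_index,
               status = status, stringsAsFactors = FALSE)
  }

  r <- (window_px - 1L) %/% 2L
  cx <- round(point[1]) + 1L  # 1-based column
  cy <- round(point[2]) + 1L  # 1-based row
  nr <- nrow(frame_t); nc <- ncol(frame_t)
  # window plus 1-px margin for the central differences
  if (cx - r - 1L < 1L || cx + r + 1L > nc ||
      cy - r - 1L < 1L || cy + r + 1L > nr) {
    return(res(NA_real_, NA_real_, "out_of_bounds"))
  }

  rows <- (cy - r):(cy + r)
  cols <- (cx - r):(cx + r)
  Ix <- (frame_t[rows, cols + 1L] - frame_t[rows, cols - 1L]) / 2
  Iy <- (frame_t[rows + 1L, cols] - frame_t[rows - 1L, cols]) / 2

  g11 <- sum(Ix * Ix); g12 <- sum(Ix * Iy); g22 <- sum(Iy * Iy)
  tr <- g11 + g22
  det <- g11 * g22 - g12 * g12
  disc <- sqrt(max(0, tr * tr / 4 - det))
  lam_min <- tr / 2 - disc
  lam_max <- tr / 2 + disc
  if (lam_min < 1e-6 || lam_max / max(lam_min, .Machine$double.xmin) > 1e6) {
    return(res(NA_real_, NA_real_, "aperture_failure"))
  }

  w0 <- frame_t[rows, cols]
  u <- 0; v <- 0
  for (it in seq_len(max(1L, iterations))) {
    warped <- bilinear_window(frame_t1, rows + v, cols + u)
    if (is.null(warped)) break  # window drifted out of bounds; keep estimate
    It <- warped - w0
    b1 <- -sum(Ix * It)
    b2 <- -sum(Iy * It)
    du <- (g22 * b1 - g12 * b2) / det
    dv <- (g11 * b2 - g12 * b1) / det
    u <- u + du
    v <- v + dv
    if (sqrt(du * du + dv * dv) < 0.01) break
  }
  res(u, v, "ok")
}

# Bilinear sample of m at the grid rows x cols (fractional 1-based
# indices); NULL when any sample would fall outside the matrix.
bilinear_window <- function(m, rows, cols) {
  if (min(rows) < 1 || max(rows) > nrow(m) ||
      min(cols) < 1 || max(cols) > ncol(m)) {
    return(NULL)
  }
  r0 <- pmin(floor(rows), nrow(m) - 1L)
  c0 <- pmin(floor(cols), ncol(m) - 1L)
  fr <- rows - r0
  fc <- cols - c0
  a <- m[r0, c0, drop = FALSE]
  b <- m[r0, c0 + 1L, drop = FALSE]
  cc <- m[r0 + 1L, c0, drop = FALSE]
  d <- m[r0 + 1L, c0 + 1L, drop = FALSE]
  wfr <- matrix(fr, length(rows), length(cols))
  wfc <- matrix(fc, length(rows), length(cols), byrow = TRUE)
  a * (1 - wfr) * (1 - wfc) + b * (1 - wfr) * wfc +
    cc * wfr * (1 - wfc) + d * wfr * wfc
}

# Accept a matrix, or an array with a channel dimension (averaged).
as_gray <- function(frame) {
  if (is.matrix(frame)) return(frame)
  if (is.array(frame) && length(dim(frame)) == 3L) {
    return(apply(frame, c(1L, 2L), mean))
  }
  stop_dtuemp("frames must be numeric matrices or 3-d arrays")
}

#' Predict a keypoint's next-frame position from its flow vector
#'
#' Advances an observed keypoint by its Lucas-Kanade flow vector to the
#' next frame: `(x + u, y + v)`, frame index incremented, source tagged
#' `"flow"`. A flow whose status is not `"ok"` cannot be used; the failure
#' is propagated so the caller can fall back to the network observation.
#'
#' @param obs one-row keypoint data frame (`frame`, `joint`, `x`, `y`).
#' @param flow one-row flow data frame from [lk_flow()].
#' @return A one-row keypoint data frame at `frame + 1` with
#'   `source = "flow"`.
#' @export
predict_next <- function(obs, flow) {
  if (!identical(flow$status, "ok")) {
    stop_dtuemp("cannot predict from flow with status '%s'", flow$status)
  }
  data.frame(frame = obs$frame + 1L, joint = obs$joint,
             x = obs$x + flow$u, y = obs$y + flow$v,
             confidence = obs$confidence %||% NA_real_, source = "flow",
             stringsAsFactors = FALSE)
}

#' Per-joint flow vectors for a whole track
#'
#' Computes Lucas-Kanade flow at the elbow and wrist coordinates of every
#' consecutive frame pair of a track, evaluated at the track's own
#' coordinates. For tracks rendered without noise this yields the exact
#' inter-frame displacement field used by the correction tests; on real
#' frames it is the flow source of the correction stage.
#'
#' @param frames list of grayscale frames (one per track frame).
#' @param track the `"trial_track"` whose coordinates seed the flow.
#' @param window_px Lucas-Kanade window (odd, pixels).
#' @return A data frame with one row per (frame pair, joint): `frame`
#'   (index t of the pair t -> t+1), `joint`, `u`, `v`, `status`.
#' @export
track_flow <- function(frames, track, window_px = 15L) {
  stopifnot(inherits(track, "trial_track"))
  if (length(frames) != track$n_frames) {
    stop_dtuemp("frame stack length (%d) does not match track (%d frames)",
                length(frames), track$n_frames)
  }
  d <- track$data
  out <- vector("list", 2L * (track$n_frames - 1L))
  k <- 0L
  for (t in seq_len(track$n_frames - 1L)) {
    for (j in c("elbow", "wrist")) {
      pt <- c(d[[paste0(j, "_x")]][t], d[[paste0(j, "_y")]][t])
      fl <- lk_flow(frames[[t]], frames[[t + 1L]], pt, window_px,
                    joint = j, frame_index = d$frame[t])
      k <- k + 1L
      out[[k]] <- fl
    }
  }
  do.call(rbind, out)
}

#' Exact displacement field of a track (reference flow)
#'
#' Finite differences of a track's own coordinates: the flow an ideal
#' estimator would return. Used as the exact synthetic flow in correction
#' tests (computed from the noise-free truth track), and as a degenerate
#' fallback when no frames are available.
#'
#' @param track a `"trial_track"`.
#' @return A flow data frame in the same shape as [track_flow()], all
#'   statuses `"ok"`.
#' @export
displacement_flow <- function(track) {
  stopifnot(inherits(track, "trial_track"))
  d <- track$data
  n <- track$n_frames
  if (n < 2L) stop_dtuemp("track must have at least 2 frames")
  t0 <- seq_len(n - 1L)
  rbind(
    data.frame(frame = d$frame[t0], joint = "elbow",
               u = diff(d$elbow_x), v = diff(d$elbow_y), status = "ok",
               stringsAsFactors = FALSE),
    data.frame(frame = d$frame[t0], joint = "wrist",
               u = diff(d$wrist_x), v = diff(d$wrist_y), status = "ok",
               stringsAsFactors = FALSE)
  )
}
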