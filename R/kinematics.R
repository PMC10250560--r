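#' Wrist-elbow rotation angle sequence of a track
#'
#' The forearm angle per frame: `theta = atan2(-(y_wrist - y_elbow),
#' x_wrist - x_elbow)` in degrees. Image coordinates have y pointing down,
#' so the sign flip makes the angle counterclockwise in the conventional
#' y-up sense: a horizontal forearm pointing right is 0 degrees and a
#' forearm pointing straight up on screen is +90. The sequence is
#' phase-unwrapped so no consecutive step exceeds 180 degrees.
#'
#' The duration metrics downstream depend only on when the angle peaks,
#' so they are invariant to the angular reference; the fixed image-axis
#' reference is chosen for reproducibility.
#'
#' @param track a `"trial_track"`.
#' @param variant which stage produced the track: `"network"`, `"flow"`,
#'   `"corrected"` or `"sensor_reference"`.
#' @return An object of class `"angle_sequence"`: list of `values`
#'   (degrees per frame), `fps`, `variant`.
#' @export
compute_angle_sequence <- function(track, variant = track$source) {
  stopifnot(inherits(track, "trial_track"))
  d <- track$data
  dx <- d$wrist_x - d$elbow_x
  dy <- d$wrist_y - d$elbow_y
  coincident <- which(dx == 0 & dy == 0)
  if (length(coincident)) {
    stop_dtuemp("wrist and elbow coincide at frame %d; angle undefined",
                d$frame[coincident[1]])
  }
  theta <- atan2(-dy, dx) * 180 / pi
  angle_sequence(unwrap_deg(theta), fps = track$fps, variant = variant)
}

#' Construct an angle sequence
#'
#' @param values angle in degrees per frame (finite).
#' @param fps frame rate in Hz (> 0).
#' @param variant stage label: `"network"`, `"flow"`, `"corrected"`,
#'   `"sensor_reference"` or `"synthetic"`.
#' @return An `"angle_sequence"` object.
#' @export
angle_sequence <- function(values, fps,
                           variant = c("corrected", "network", "flow",
                                       "sensor_reference", "synthetic")) {
  variant <- match.arg(variant)
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop_dtuemp("angle values must be finite")
  check_number(fps, "fps", lower = 0, strict_lower = TRUE)
  structure(list(values = values, fps = fps, variant = variant),
            class = "angle_sequence")
}

#' @export
print.angle_sequence <- function(x, ...) {
  cat(sprintf("Angle sequence (%s): %d frames @ %g fps, %.1f to %.1f deg\n",
              x$variant, length(x$values), x$fps,
              min(x$values), max(x$values)))
  invisible(x)
}

# Interior local extrema of v with the given prominence and minimum
# separation (frames, 1-based indices). kind is +1 for maxima, -1 minima.
find_extrema <- function(v, kind, prominence, min_separation) {
  s <- kind * v
  n <- length(s)
  # local maxima of s, plateau-aware: first index of each plateau that
  # rises before and falls after
  d <- diff(s)
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (s[i] > s[i - 1L]) {
      j <- i
      while (j < n && s[j + 1L] == s[j]) j <- j + 1L
      if (j < n && s[j + 1L] < s[j]) cand <- c(cand, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(cand)) return(integer(0))
  # prominence: drop to the highest of the two key saddles
  prom <- vapply(cand, function(p) {
    left <- min(s[max(1L, find_higher(s, p, -1L)):p])
    right <- min(s[p:min(n, find_higher(s, p, +1L))])
    s[p] - max(left, right)
  }, numeric(1))
  keep <- cand[prom >= prominence]
  # enforce separation greedily, highest peaks first
  if (length(keep) > 1L && min_separation > 1L) {
    ord <- keep[order(s[keep], decreasing = TRUE)]
    chosen <- integer(0)
    for (p in ord) {
      if (!length(chosen) || all(abs(chosen - p) >= min_separation)) {
        chosen <- c(chosen, p)
      }
    }
    keep <- sort(chosen)
  }
  keep
}

# Index of the nearest strictly higher sample in the given direction, or
# the sequence end if none (used to bound prominence saddles).
find_higher <- function(s, p, dir) {
  i <- p + dir
  n <- length(s)
  while (i >= 1L && i <= n) {
    if (s[i] > s[p]) return(i)
    i <- i + dir
  }
  if (dir < 0) 1L else n
}

#' Segment an angle sequence into flexion and extension phases
#'
#' Local peak segmentation: locate the local maxima and minima of the
#' angle sequence, then mark the span from each local minimum to the next
#' maximum as a flexion phase and from each maximum to the next minimum
#' as an extension phase. Strict alternation is enforced by keeping, of
#' several consecutive maxima with no intervening minimum, only the
#' highest (and symmetrically the lowest of consecutive minima); ties
#' keep the earliest. Samples before the first and after the last
#' retained extremum belong to no phase.
#'
#' A trial of this protocol starts and ends at rest, i.e. at an extreme
#' of the movement, so a sequence endpoint lying essentially at the
#' signal's extreme value is itself a phase boundary. An endpoint is
#' therefore included as a peak when it is within
#' `endpoint_tol_frac` of the signal range of the corresponding global
#' extreme (and clears the prominence requirement against the first or
#' last interior extremum); an endpoint elsewhere in the range — a
#' recording started mid-movement — is not a boundary, and the partial
#' phase it belongs to is discarded.
#'
#' @param a an `"angle_sequence"` (or numeric vector with `fps` supplied).
#' @param prominence_deg minimum peak prominence in degrees; rejects
#'   jitter-scale wiggles (default 10).
#' @param min_separation_frames minimum spacing between same-kind peaks in
#'   frames (default 5, about 0.17 s at 30 FPS).
#' @param endpoint_tol_frac fraction of the signal range within which a
#'   sequence endpoint counts as lying at an extreme (default 0.05).
#' @param fps frame rate, only when `a` is a bare numeric vector.
#' @return A `"phase_set"`: data frame of `kind`, `start_frame`,
#'   `end_frame` (zero-based), `duration_s`, with `fps` attribute. Fewer
#'   than one max-min pair yields an empty phase set with a message.
#' @export
segment_phases <- function(a, prominence_deg = 10, min_separation_frames = 5,
                           endpoint_tol_frac = 0.05, fps = NULL) {
  if (!inherits(a, "angle_sequence")) {
    if (is.null(fps)) stop_dtuemp("supply an angle_sequence or fps")
    a <- angle_sequence(a, fps = fps, variant = "corrected")
  }
  v <- a$values
  if (length(v) < 3L) stop_dtuemp("need at least 3 samples to segment")

  maxima <- find_extrema(v, +1L, prominence_deg, min_separation_frames)
  minima <- find_extrema(v, -1L, prominence_deg, min_separation_frames)

  empty <- function() {
    message("no max-min peak pair found; empty phase set")
    structure(data.frame(kind = character(0), start_frame = integer(0),
                         end_frame = integer(0), duration_s = numeric(0),
                         stringsAsFactors = FALSE),
              fps = a$fps, class = c("phase_set", "data.frame"))
  }
  if (!length(maxima) || !length(minima)) return(empty())

  ext <- rbind(data.frame(idx = maxima, kind = "max"),
               data.frame(idx = minima, kind = "min"))
  ext <- ext[order(ext$idx), ]
  # strict alternation: among consecutive same-kind extrema keep the most
  # extreme (earliest on ties)
  keep <- logical(nrow(ext))
  i <- 1L
  while (i <= nrow(ext)) {
    j <- i
    while (j < nrow(ext) && ext$kind[j + 1L] == ext$kind[i]) j <- j + 1L
    grp <- i:j
    vals <- v[ext$idx[grp]]
    best <- if (ext$kind[i] == "max") grp[which.max(vals)] else
      grp[which.min(vals)]
    keep[best] <- TRUE
    i <- j + 1L
  }
  ext <- ext[keep, ]
  if (nrow(ext) < 1L) return(empty())

  # endpoint boundaries: a trial starting or ending at rest sits at an
  # extreme of the movement
  n <- length(v)
  tol <- endpoint_tol_frac * (max(v) - min(v))
  first <- ext[1L, ]
  if (first$idx > 1L) {
    if (first$kind == "max" && v[1L] <= min(v) + tol &&
        v[first$idx] - v[1L] >= prominence_deg) {
      ext <- rbind(data.frame(idx = 1L, kind = "min"), ext)
    } else if (first$kind == "min" && v[1L] >= max(v) - tol &&
               v[1L] - v[first$idx] >= prominence_deg) {
      ext <- rbind(data.frame(idx = 1L, kind = "max"), ext)
    }
  }
  last <- ext[nrow(ext), ]
  if (last$idx < n) {
    if (last$kind == "max" && v[n] <= min(v) + tol &&
        v[last$idx] - v[n] >= prominence_deg) {
      ext <- rbind(ext, data.frame(idx = n, kind = "min"))
    } else if (last$kind == "min" && v[n] >= max(v) - tol &&
               v[n] - v[last$idx] >= prominence_deg) {
      ext <- rbind(ext, data.frame(idx = n, kind = "max"))
    }
  }
  if (nrow(ext) < 2L) return(empty())

  starts <- ext$idx[-nrow(ext)]
  ends <- ext$idx[-1L]
  kind <- ifelse(ext$kind[-nrow(ext)] == "min", "flexion", "extension")
  ps <- data.frame(kind = kind,
                   start_frame = starts - 1L,  # zero-based frames
                   end_frame = ends - 1L,
                   duration_s = (ends - starts) / a$fps,
                   stringsAsFactors = FALSE)
  structure(ps, fps = a$fps, class = c("phase_set", "data.frame"))
}

#' The six DTUEMP metrics of a phase set
#'
#' Mean and sample SD (n - 1 denominator) of the flexion-phase durations,
#' the extension-phase durations, and the flexion-extension cycle
#' durations. A cycle pairs each flexion phase with the extension phase
#' that immediately follows it; its duration is exactly the sum of the
#' two member phases. A phase kind observed fewer than two times yields
#' its mean from the available data and an `NA` SD; an empty phase set
#' yields all-`NA` metrics with a warning.
#'
#' @param p a `"phase_set"` from [segment_phases()].
#' @return An object of class `"dtuemp_metrics"`: named list
#'   `flex_mean_s`, `flex_sd_s`, `ext_mean_s`, `ext_sd_s`,
#'   `cycle_mean_s`, `cycle_sd_s` (all seconds), plus phase counts.
#' @export
compute_metrics <- function(p) {
  if (!inherits(p, "phase_set")) stop_dtuemp("'p' must be a phase_set")
  if (nrow(p) == 0L) {
    warning("empty phase set; all metrics are NA", call. = FALSE)
    return(structure(list(flex_mean_s = NA_real_, flex_sd_s = NA_real_,
                          ext_mean_s = NA_real_, ext_sd_s = NA_real_,
                          cycle_mean_s = NA_real_, cycle_sd_s = NA_real_,
                          n_flexion = 0L, n_extension = 0L, n_cycles = 0L),
                     class = "dtuemp_metrics"))
  }
  flex <- p$duration_s[p$kind == "flexion"]
  ext <- p$duration_s[p$kind == "extension"]
  # cycles: each flexion phase plus the immediately following extension
  flex_rows <- which(p$kind == "flexion")
  cyc <- numeric(0)
  for (i in flex_rows) {
    if (i < nrow(p) && p$kind[i + 1L] == "extension") {
      cyc <- c(cyc, p$duration_s[i] + p$duration_s[i + 1L])
    }
  }
  m <- function(x) if (length(x)) mean(x) else NA_real_
  s <- function(x) if (length(x) >= 2L) stats::sd(x) else NA_real_
  structure(list(
    flex_mean_s = m(flex), flex_sd_s = s(flex),
    ext_mean_s = m(ext), ext_sd_s = s(ext),
    cycle_mean_s = m(cyc), cycle_sd_s = s(cyc),
    n_flexion = length(flex), n_extension = length(ext),
    n_cycles = length(cyc)
  ), class = "dtuemp_metrics")
}

#' @export
print.dtuemp_metrics <- function(x, ...) {
  cat("DTUEMP metrics (seconds):\n")
  cat(sprintf("  flexion:           mean %s, SD %s  (n = %d)\n",
              fmt_s(x$flex_mean_s), fmt_s(x$flex_sd_s), x$n_flexion))
  cat(sprintf("  extension:         mean %s, SD %s  (n = %d)\n",
              fmt_s(x$ext_mean_s), fmt_s(x$ext_sd_s), x$n_extension))
  cat(sprintf("  flexion-extension: mean %s, SD %s  (n = %d)\n",
              fmt_s(x$cycle_mean_s), fmt_s(x$cycle_sd_s), x$n_cycles))
  invisible(x)
}

fmt_s <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)

#' @export
as.data.frame.dtuemp_metrics <- function(x, ...) {
  data.frame(flex_mean_s = x$flex_mean_s, flex_sd_s = x$flex_sd_s,
             ext_mean_s = x$ext_mean_s, ext_sd_s = x$ext_sd_s,
             cycle_mean_s = x$cycle_mean_s, cycle_sd_s = x$cycle_sd_s)
}

#' Truth metrics of a generated trial
#'
#' The six DTUEMP metrics computed directly from a trial's ground-truth
#' phase table — the oracle the video-derived metrics are compared to.
#'
#' @param trial a `"gt_trial"`.
#' @return A `"dtuemp_metrics"` object.
#' @export
truth_metrics <- function(trial) {
  stopifnot(inherits(trial, "gt_trial"))
  ps <- structure(trial$phase_truth, fps = trial$fps,
                  class = c("phase_set", "data.frame"))
  compute_metrics(ps)
}
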