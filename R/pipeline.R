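#' Pipeline configuration
#'
#' Assembles and validates the settings of every stage of
#' [run_pipeline()]. Unknown keys are rejected, so a typo in a config
#' file cannot silently fall back to a default.
#'
#' @param fps frame rate in Hz.
#' @param flow list: `window_px` (odd Lucas-Kanade window).
#' @param correction list: `disagreement_threshold`, `threshold_mode`,
#'   `max_consecutive_substitutions` (see [correction_config()]).
#' @param segmentation list: `prominence_deg`, `min_separation_frames`,
#'   `smooth` (logical; apply a 5-frame moving average before
#'   segmentation, off by default so results are bit-reproducible from
#'   the correction stage).
#' @param seed integer seed recorded in provenance.
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(fps = 30,
                            flow = list(window_px = 15L),
                            correction = list(disagreement_threshold = 0.25,
                                              threshold_mode = "relative",
                                              max_consecutive_substitutions = 1L),
                            segmentation = list(prominence_deg = 10,
                                                min_separation_frames = 5,
                                                smooth = FALSE),
                            seed = 1L) {
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) stop_dtuemp("unknown %s config key(s): %s", where,
                                 paste(bad, collapse = ", "))
  }
  check_keys(flow, "window_px", "flow")
  check_keys(correction, c("disagreement_threshold", "threshold_mode",
                           "max_consecutive_substitutions"), "correction")
  check_keys(segmentation, c("prominence_deg", "min_separation_frames",
                             "smooth"), "segmentation")
  defaults <- list(window_px = 15L)
  flow <- utils::modifyList(defaults, flow)
  correction <- utils::modifyList(
    list(disagreement_threshold = 0.25, threshold_mode = "relative",
         max_consecutive_substitutions = 1L), correction)
  segmentation <- utils::modifyList(
    list(prominence_deg = 10, min_separation_frames = 5, smooth = FALSE),
    segmentation)
  check_number(fps, "fps", lower = 0, strict_lower = TRUE)
  structure(list(fps = fps, flow = flow, correction = correction,
                 segmentation = segmentation, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys match the arguments of
#'   [pipeline_config()]; unknown keys are rejected.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  bad <- setdiff(names(y), c("fps", "flow", "correction", "segmentation",
                             "seed"))
  if (length(bad)) stop_dtuemp("unknown config key(s): %s",
                               paste(bad, collapse = ", "))
  do.call(pipeline_config, y)
}

#' Run the video-metrics pipeline on a keypoint track
#'
#' Executes correct -> angles -> segment -> metrics on a network keypoint
#' track. Flow can come from rendered frames (Lucas-Kanade at the track's
#' coordinates), or be supplied directly as a flow table; with neither,
#' the correction stage is skipped and the network angles are used
#' as-is (noted in the result).
#'
#' When `out_dir` is given, the stage artifacts are written there:
#' `angles.csv`, `metrics.csv`, `correction_report.json` and
#' `provenance.json` (package version, config, config hash and seed —
#' enough to reproduce the outputs byte for byte).
#'
#' @param track a `"trial_track"` or path to a keypoint CSV.
#' @param config a [pipeline_config()].
#' @param frames optional list of grayscale frames for the flow stage.
#' @param flow optional precomputed flow table (overrides `frames`).
#' @param subject subject identifier written to the metrics table.
#' @param out_dir optional output directory.
#' @return A list: `metrics` (`"dtuemp_metrics"`), `phases`, `angles`,
#'   `track` (corrected), `report` (correction report or NULL),
#'   `corrected` (logical).
#' @export
run_pipeline <- function(track, config = pipeline_config(), frames = NULL,
                         flow = NULL, subject = 1L, out_dir = NULL) {
  if (is.character(track)) track <- ingest_track(track, fps = config$fps)
  stopifnot(inherits(track, "trial_track"))

  corrected <- FALSE
  report <- NULL
  if (is.null(flow) && !is.null(frames)) {
    flow <- track_flow(frames, track, window_px = config$flow$window_px)
  }
  if (!is.null(flow)) {
    cc <- correction_config(
      disagreement_threshold = config$correction$disagreement_threshold,
      threshold_mode = config$correction$threshold_mode,
      max_consecutive_substitutions =
        config$correction$max_consecutive_substitutions)
    res <- correct_track(track, flow, cc)
    track <- res$track
    report <- res$report
    corrected <- TRUE
  }

  angles <- compute_angle_sequence(track,
                                   variant = if (corrected) "corrected"
                                   else "network")
  values <- angles$values
  if (isTRUE(config$segmentation$smooth)) {
    values <- moving_average(values, 5L)
    angles <- angle_sequence(values, fps = angles$fps,
                             variant = angles$variant)
  }
  phases <- segment_phases(
    angles,
    prominence_deg = config$segmentation$prominence_deg,
    min_separation_frames = config$segmentation$min_separation_frames)
  metrics <- compute_metrics(phases)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_angles(angles, file.path(out_dir, "angles.csv"))
    write_metrics(cbind(subject = subject, as.data.frame(metrics)),
                  file.path(out_dir, "metrics.csv"))
    if (!is.null(report)) {
      jsonlite::write_json(
        list(threshold_px = report$threshold_px,
             n_frames = report$n_frames,
             elbow_substituted = report$elbow$substituted_frames,
             wrist_substituted = report$wrist$substituted_frames),
        file.path(out_dir, "correction_report.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    cfg_yaml <- yaml::as.yaml(unclass(config))
    tf <- tempfile()
    writeLines(cfg_yaml, tf)
    hash <- unname(tools::md5sum(tf))
    unlink(tf)
    jsonlite::write_json(
      list(package = "dtuemp",
           version = as.character(utils::packageVersion("dtuemp")),
           config = unclass(config), config_md5 = hash,
           seed = config$seed, corrected = corrected),
      file.path(out_dir, "provenance.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(metrics = metrics, phases = phases, angles = angles, track = track,
       report = report, corrected = corrected)
}

# Centred moving average with shrinking windows at the edges.
moving_average <- function(v, width = 5L) {
  r <- width %/% 2L
  n <- length(v)
  vapply(seq_len(n), function(i) {
    mean(v[max(1L, i - r):min(n, i + r)])
  }, numeric(1))
}
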