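# Readers and writers for the plain-text artifact formats. All files are
# UTF-8 CSV with '.' decimal separator and a single header line; numbers
# are written at full double precision so write -> read round-trips
# exactly. Readers key on column names, so column order is free, but
# missing or unexpected columns are errors.

write_csv_full <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  out <- df
  for (j in which(num)) out[[j]] <- format_full(df[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# Whole-valued doubles print without a decimal point and would read back
# as integer; numeric payload columns are coerced to double explicitly.
as_double_cols <- function(df, cols) {
  for (j in intersect(cols, names(df))) df[[j]] <- as.numeric(df[[j]])
  df
}

check_schema <- function(df, expected, path, extra_ok = FALSE) {
  miss <- setdiff(expected, names(df))
  extra <- setdiff(names(df), expected)
  if (length(miss) || (!extra_ok && length(extra))) {
    stop_dtuemp("'%s': schema mismatch (missing: %s; unexpected: %s)",
                path,
                if (length(miss)) paste(miss, collapse = ", ") else "none",
                if (length(extra)) paste(extra, collapse = ", ") else "none")
  }
  df[expected]
}

#' Write and read keypoint tracks
#'
#' Keypoint CSV: long format with columns `frame,joint,x,y,confidence,flag`
#' (`flag` is 1 for frames whose observation was flagged as an injected or
#' detected outlier). `ingest_track()` validates that both joints are
#' present in every frame and that frame indices are contiguous from 0.
#'
#' @param track a `"trial_track"`.
#' @param path CSV file path.
#' @return `write_track()` returns the path invisibly; `ingest_track()` a
#'   `"trial_track"`.
#' @export
write_track <- function(track, path) {
  stopifnot(inherits(track, "trial_track"))
  d <- track$data
  long <- rbind(
    data.frame(frame = d$frame, joint = "elbow", x = d$elbow_x,
               y = d$elbow_y,
               confidence = d$elbow_confidence %||% rep(NA_real_, nrow(d)),
               flag = as.integer(d$elbow_outlier %||% logical(nrow(d)))),
    data.frame(frame = d$frame, joint = "wrist", x = d$wrist_x,
               y = d$wrist_y,
               confidence = d$wrist_confidence %||% rep(NA_real_, nrow(d)),
               flag = as.integer(d$wrist_outlier %||% logical(nrow(d))))
  )
  long <- long[order(long$frame, long$joint), ]
  write_csv_full(long, path)
}

#' @rdname write_track
#' @param fps frame rate of the recording, Hz.
#' @export
ingest_track <- function(path, fps = 30) {
  if (!file.exists(path)) stop_dtuemp("'%s': no such file", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- check_schema(df, c("frame", "joint", "x", "y", "confidence", "flag"),
                     path)
  df <- as_double_cols(df, c("x", "y", "confidence"))
  if (nrow(df) == 0L) stop_dtuemp("'%s': empty track (header only)", path)
  frames <- sort(unique(df$frame))
  if (!identical(as.integer(frames), seq_len(length(frames)) - 1L)) {
    stop_dtuemp("'%s': frame indices must be contiguous from 0", path)
  }
  if (is.unsorted(df$frame)) {
    stop_dtuemp("'%s': non-monotone frame indices", path)
  }
  for (fr in frames) {
    here <- df$joint[df$frame == fr]
    for (j in c("elbow", "wrist")) {
      if (sum(here == j) != 1L) {
        stop_dtuemp("frame %d: missing joint %s", fr, j)
      }
    }
  }
  el <- df[df$joint == "elbow", ][order(df$frame[df$joint == "elbow"]), ]
  wr <- df[df$joint == "wrist", ][order(df$frame[df$joint == "wrist"]), ]
  dat <- data.frame(frame = el$frame,
                    elbow_x = el$x, elbow_y = el$y,
                    wrist_x = wr$x, wrist_y = wr$y,
                    elbow_confidence = el$confidence,
                    wrist_confidence = wr$confidence,
                    elbow_outlier = el$flag == 1L,
                    wrist_outlier = wr$flag == 1L)
  new_trial_track(dat, fps = fps, source = "network")
}

#' Write and read ground-truth angle files
#'
#' Truth CSV: `frame,theta_deg`, one row per frame.
#'
#' @param trial a `"gt_trial"`.
#' @param path CSV file path.
#' @export
write_truth <- function(trial, path) {
  stopifnot(inherits(trial, "gt_trial"))
  write_csv_full(data.frame(frame = seq_along(trial$theta_true) - 1L,
                            theta_deg = trial$theta_true), path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- check_schema(df, c("frame", "theta_deg"), path)
  as.numeric(df$theta_deg)
}

#' Write and read angle sequences
#'
#' Angle CSV: `frame,theta_deg,variant`.
#'
#' @param a an `"angle_sequence"`.
#' @param path CSV file path.
#' @export
write_angles <- function(a, path) {
  stopifnot(inherits(a, "angle_sequence"))
  write_csv_full(data.frame(frame = seq_along(a$values) - 1L,
                            theta_deg = a$values, variant = a$variant), path)
}

#' @rdname write_angles
#' @param fps frame rate, Hz.
#' @export
read_angles <- function(path, fps = 30) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- check_schema(df, c("frame", "theta_deg", "variant"), path)
  if (nrow(df) == 0L) stop_dtuemp("'%s': empty angle file", path)
  angle_sequence(as.numeric(df$theta_deg), fps = fps, variant = df$variant[1])
}

#' Write and read per-subject metrics tables
#'
#' Metrics CSV: one row per subject with the six DTUEMP metric columns.
#'
#' @param df data frame with columns `subject`, `flex_mean_s`,
#'   `flex_sd_s`, `ext_mean_s`, `ext_sd_s`, `cycle_mean_s`, `cycle_sd_s`.
#' @param path CSV file path.
#' @export
write_metrics <- function(df, path) {
  cols <- c("subject", "flex_mean_s", "flex_sd_s", "ext_mean_s",
            "ext_sd_s", "cycle_mean_s", "cycle_sd_s")
  df <- check_schema(as.data.frame(df), cols, path, extra_ok = TRUE)
  write_csv_full(df, path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- check_schema(df, c("subject", "flex_mean_s", "flex_sd_s",
                           "ext_mean_s", "ext_sd_s", "cycle_mean_s",
                           "cycle_sd_s"), path)
  as_double_cols(df, c("flex_mean_s", "flex_sd_s", "ext_mean_s",
                       "ext_sd_s", "cycle_mean_s", "cycle_sd_s"))
}

#' Write and read cohort tables
#'
#' Cohort CSV: `subject`, the `metric_*` predictors, `age`, `sex`, `bmi`,
#' `mmse`, `tug`.
#'
#' @param cohort a `"cohort_table"` or conforming data frame.
#' @param path CSV file path.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  need <- c("subject", grep("^metric_", names(df), value = TRUE),
            "age", "sex", "bmi", "mmse", "tug")
  df <- check_schema(df, need, path)
  write_csv_full(df, path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  metrics <- grep("^metric_", names(df), value = TRUE)
  if (!length(metrics)) stop_dtuemp("'%s': no metric_* columns", path)
  df <- check_schema(df, c("subject", metrics, "age", "sex", "bmi",
                           "mmse", "tug"), path)
  df <- as_double_cols(df, c(metrics, "age", "bmi", "mmse", "tug"))
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write and read flow tables
#'
#' Flow CSV: `frame,joint,u,v,status`, one row per (frame pair, joint).
#'
#' @param flow a flow data frame ([track_flow()] / [displacement_flow()]).
#' @param path CSV file path.
#' @export
write_flow <- function(flow, path) {
  flow <- check_schema(as.data.frame(flow),
                       c("frame", "joint", "u", "v", "status"), path,
                       extra_ok = TRUE)
  write_csv_full(flow, path)
}

#' @rdname write_flow
#' @export
read_flow <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_double_cols(check_schema(df, c("frame", "joint", "u", "v", "status"),
                              path), c("u", "v"))
}
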