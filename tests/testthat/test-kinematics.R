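make_track <- function(elbow, wrist, fps = 30) {
  d <- data.frame(frame = seq_len(nrow(wrist)) - 1L,
                  elbow_x = elbow[, 1], elbow_y = elbow[, 2],
                  wrist_x = wrist[, 1], wrist_y = wrist[, 2],
                  elbow_confidence = 1, wrist_confidence = 1,
                  elbow_outlier = FALSE, wrist_outlier = FALSE)
  dtuemp:::new_trial_track(d, fps = fps)
}

test_that("angle convention: y-down image axis, counterclockwise positive", {
  e <- matrix(c(0, 0), 1, 2)
  expect_equal(compute_angle_sequence(
    make_track(e, matrix(c(1, 0), 1, 2)))$values, 0)
  # wrist above the elbow on screen (smaller y) is +90
  expect_equal(compute_angle_sequence(
    make_track(e, matrix(c(0, -1), 1, 2)))$values, 90)
  expect_equal(compute_angle_sequence(
    make_track(matrix(c(2, 3), 1, 2), matrix(c(5, 7), 1, 2)))$values,
    atan2(-4, 3) * 180 / pi)
  expect_equal(atan2(-4, 3) * 180 / pi, -53.1301, tolerance = 1e-4)
})

test_that("coincident joints error with the frame index", {
  e <- matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE)
  w <- matrix(c(1, 0, 5, 5), 2, 2, byrow = TRUE)
  expect_error(compute_angle_sequence(make_track(e, w)), "frame 1")
})

test_that("unwrapping keeps consecutive steps under 180 degrees", {
  # a full rotation crosses the atan2 branch cut
  th <- seq(0, 4 * pi, length.out = 200)
  e <- matrix(0, 200, 2)
  w <- cbind(cos(th), -sin(th))
  a <- compute_angle_sequence(make_track(e, w))
  expect_true(all(abs(diff(a$values)) < 180))
  expect_equal(max(a$values) - min(a$values), 720, tolerance = 1e-6)
})

test_that("sinusoid segments into half-period phases", {
  t <- seq(0, 20, by = 1 / 30)[1:600]
  a <- angle_sequence(60 + 60 * sin(2 * pi * 0.5 * t), fps = 30)
  ps <- segment_phases(a)
  expect_true(all(abs(ps$duration_s - 1) <= 1 / 30 + 1e-9))
  expect_true(all(ps$kind[-1] != ps$kind[-nrow(ps)]))
})

test_that("monotone ramps yield an empty phase set", {
  a <- angle_sequence(seq(0, 100, length.out = 50), fps = 30)
  expect_message(ps <- segment_phases(a), "empty phase set")
  expect_equal(nrow(ps), 0L)
  expect_warning(m <- compute_metrics(ps), "empty")
  expect_true(is.na(m$flex_mean_s))
})

test_that("segmentation recovers generator phase boundaries within 1 frame", {
  for (i in 1:100) {
    trial <- generate_trial(trial_spec(cycle_period_sd_s = 0.15, seed = i))
    a <- angle_sequence(trial$theta_true, fps = trial$fps)
    ps <- segment_phases(a)
    truth <- trial$phase_truth
    # align: compare each detected boundary to the nearest truth boundary
    tb <- sort(unique(c(truth$start_frame, truth$end_frame)))
    db <- sort(unique(c(ps$start_frame, ps$end_frame)))
    for (b in db) expect_lte(min(abs(tb - b)), 1)
    # detected phase durations match truth durations for interior phases
    expect_gte(nrow(ps), nrow(truth) - 3)
  }
})

test_that("segmentation is invariant to offsets and flips labels on negation", {
  trial <- generate_trial(trial_spec(seed = 12))
  a <- trial$theta_true
  ps1 <- segment_phases(angle_sequence(a, fps = 30))
  ps2 <- segment_phases(angle_sequence(a + 500, fps = 30))
  expect_equal(ps1$start_frame, ps2$start_frame)
  expect_equal(ps1$kind, ps2$kind)
  ps3 <- segment_phases(angle_sequence(-a, fps = 30))
  expect_equal(ps1$start_frame, ps3$start_frame)
  expect_equal(ps3$kind,
               ifelse(ps1$kind == "flexion", "extension", "flexion"))
})

test_that("metrics follow the hand-computed examples", {
  ps <- structure(data.frame(
    kind = rep(c("flexion", "extension"), 4),
    start_frame = seq(0, 210, by = 30),
    end_frame = seq(30, 240, by = 30),
    duration_s = rep(1, 8)), fps = 30,
    class = c("phase_set", "data.frame"))
  m <- compute_metrics(ps)
  expect_equal(m$flex_mean_s, 1)
  expect_equal(m$ext_mean_s, 1)
  expect_equal(m$cycle_mean_s, 2)
  expect_equal(c(m$flex_sd_s, m$ext_sd_s, m$cycle_sd_s), c(0, 0, 0))

  ps2 <- structure(data.frame(
    kind = c("flexion", "extension", "flexion", "extension"),
    start_frame = c(0, 24, 54, 90),
    end_frame = c(24, 54, 90, 120),
    duration_s = c(0.8, 1.0, 1.2, 1.0)), fps = 30,
    class = c("phase_set", "data.frame"))
  m2 <- compute_metrics(ps2)
  expect_equal(m2$flex_mean_s, 1)
  expect_equal(m2$flex_sd_s, 0.28284, tolerance = 1e-4)
  expect_equal(m2$flex_sd_s, sd(c(0.8, 1.2)))
  # cycles pair each flexion with the following extension, exactly summed
  expect_equal(m2$n_cycles, 2L)
  expect_equal(m2$cycle_mean_s, mean(c(1.8, 2.2)))
})

test_that("cycle metrics track the generator's period distribution", {
  stats <- t(vapply(1:200, function(i) {
    trial <- generate_trial(trial_spec(cycle_period_sd_s = 0.15, seed = i))
    m <- compute_metrics(segment_phases(
      angle_sequence(trial$theta_true, fps = 30)))
    c(m$cycle_mean_s, m$cycle_sd_s)
  }, numeric(2)))
  expect_lt(abs(mean(stats[, 1]) - 2), 2 / 30)
  pooled_sd <- mean(stats[, 2])
  # E[sample SD] of ~10 N(2, 0.15) draws is slightly below 0.15; allow
  # 3 x the between-trial SE plus the small-sample bias margin
  se <- sd(stats[, 2]) / sqrt(200)
  expect_lt(abs(pooled_sd - 0.15), 3 * se + 0.01)
})

test_that("end-to-end zero-noise metrics equal truth within quantisation", {
  for (i in c(3, 17)) {
    spec <- trial_spec(jitter_sd_px = 0, outlier_rate = 0,
                       cycle_period_sd_s = 0.2, seed = i)
    trial <- generate_trial(spec)
    track <- render_keypoints(trial)
    got <- compute_metrics(segment_phases(compute_angle_sequence(track)))
    want <- truth_metrics(trial)
    for (f in c("flex_mean_s", "ext_mean_s", "cycle_mean_s")) {
      expect_lt(abs(got[[f]] - want[[f]]), 1 / 30)
    }
  }
})
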