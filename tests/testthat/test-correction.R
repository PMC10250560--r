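test_that("clean tracks pass through unchanged", {
  spec <- trial_spec(jitter_sd_px = 0, outlier_rate = 0, seed = 8)
  track <- render_keypoints(generate_trial(spec))
  res <- correct_track(track, displacement_flow(track))
  expect_equal(res$track$data$wrist_x, track$data$wrist_x)
  expect_equal(res$track$data$elbow_y, track$data$elbow_y)
  expect_length(res$report$wrist$substituted_frames, 0)
  expect_length(res$report$elbow$substituted_frames, 0)
})

test_that("an isolated large outlier is replaced by the flow prediction", {
  fx <- outlier_fixture(seed = 21, outlier_rate = 0, jitter = 0.5)
  net <- fx$network
  truth_xy <- render_keypoints(generate_trial(
    trial_spec(jitter_sd_px = 0, outlier_rate = 0, seed = 21)))$data
  k <- 100L  # zero-based frame of the injected outlier
  i <- k + 1L
  net$data$wrist_x[i] <- net$data$wrist_x[i] + 80
  cfg <- correction_config(disagreement_threshold = 20,
                           threshold_mode = "absolute")
  res <- correct_track(net, fx$flow, cfg)
  expect_equal(res$report$wrist$substituted_frames, k)
  # corrected wrist lands within jitter scale of the truth
  err <- sqrt((res$track$data$wrist_x[i] - truth_xy$wrist_x[i])^2 +
                (res$track$data$wrist_y[i] - truth_xy$wrist_y[i])^2)
  expect_lt(err, 4 * 0.5 + 1)
  # neighbours untouched
  expect_equal(res$track$data$wrist_x[i - 1], net$data$wrist_x[i - 1])
  expect_equal(res$track$data$wrist_x[i + 1], net$data$wrist_x[i + 1])
})

test_that("two consecutive outliers: only the first is substituted", {
  # 5-frame hand fixture, wrist moving right 10 px/frame
  d <- data.frame(frame = 0:4,
                  elbow_x = 0, elbow_y = 0,
                  wrist_x = c(100, 110, 120, 130, 140),
                  wrist_y = 0,
                  elbow_confidence = 1, wrist_confidence = 1,
                  elbow_outlier = FALSE, wrist_outlier = FALSE)
  flow <- rbind(
    data.frame(frame = 0:3, joint = "elbow", u = 0, v = 0, status = "ok"),
    data.frame(frame = 0:3, joint = "wrist", u = 10, v = 0, status = "ok"))
  d$wrist_x[3] <- 200  # frames 2 and 3 corrupted
  d$wrist_x[4] <- 210
  net <- dtuemp:::new_trial_track(d, fps = 30)
  cfg <- correction_config(disagreement_threshold = 20,
                           threshold_mode = "absolute")
  res <- correct_track(net, flow, cfg)
  # hand trace: frame 2 disagrees (200 vs prediction 120) -> substituted
  # with 120; frame 3 disagrees (210 vs 130) but follows a substitution
  # -> network accepted (assumption boundary); frame 4's prediction is
  # chained from that accepted coordinate (210 + 10 = 220) and disagrees
  # with the network's 140, so it is substituted again -- an isolated run
  expect_equal(res$report$wrist$substituted_frames, c(2L, 4L))
  expect_equal(res$track$data$wrist_x, c(100, 110, 120, 210, 220))
  subs <- res$report$wrist$substituted_frames
  expect_true(all(diff(sort(subs)) > 1))  # no length-2 run
})

test_that("flow failures fall back to the network coordinate", {
  d <- data.frame(frame = 0:2, elbow_x = 0, elbow_y = 0,
                  wrist_x = c(10, 300, 30), wrist_y = 0,
                  elbow_confidence = 1, wrist_confidence = 1,
                  elbow_outlier = FALSE, wrist_outlier = FALSE)
  flow <- rbind(
    data.frame(frame = 0:1, joint = "elbow", u = 0, v = 0, status = "ok"),
    data.frame(frame = 0:1, joint = "wrist", u = 10, v = 0,
               status = c("aperture_failure", "ok")))
  net <- dtuemp:::new_trial_track(d, fps = 30)
  cfg <- correction_config(disagreement_threshold = 5,
                           threshold_mode = "absolute")
  res <- correct_track(net, flow, cfg)
  # frame 1: flow failed -> network accepted despite the jump
  expect_equal(res$track$data$wrist_x[2], 300)
  # frame 2: flow ok, prediction 310 vs network 30 -> substituted
  expect_equal(res$report$wrist$substituted_frames, 2L)
  expect_equal(res$track$data$wrist_x[3], 310)
})

test_that("angle error reduction has its fixed points", {
  truth <- c(0, 10, 20, 30)
  noisy <- truth + c(0, 5, -5, 0)
  expect_equal(angle_error_reduction(truth, noisy, truth)$reduction, 1)
  expect_equal(angle_error_reduction(truth, noisy, noisy)$reduction, 0)
  expect_error(angle_error_reduction(numeric(0), numeric(0), numeric(0)),
               "non-empty")
})

test_that("correction recovers at least 80% of the outlier-driven angle error", {
  reductions <- vapply(1:100, function(i) {
    fx <- outlier_fixture(seed = i)
    res <- correct_track(fx$network, fx$flow)
    aN <- compute_angle_sequence(fx$network, variant = "network")
    aC <- compute_angle_sequence(res$track, variant = "corrected")
    # run-length constraint holds in every trial
    for (j in c("elbow", "wrist")) {
      sf <- sort(res$report[[j]]$substituted_frames)
      if (length(sf) > 1) expect_true(all(diff(sf) > 1))
    }
    angle_error_reduction(fx$trial$theta_true, aN, aC)$reduction
  }, numeric(1))
  expect_gte(mean(reductions), 0.8)
})

test_that("raising the threshold never increases the substitution count", {
  fx <- outlier_fixture(seed = 31)
  counts <- vapply(c(10, 20, 40, 80, 160), function(th) {
    res <- correct_track(fx$network, fx$flow,
                         correction_config(th, "absolute"))
    length(res$report$wrist$substituted_frames) +
      length(res$report$elbow$substituted_frames)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("clean low-jitter tracks stay below 1% substitutions", {
  for (i in 1:5) {
    spec <- trial_spec(jitter_sd_px = 1, outlier_rate = 0, seed = 40 + i)
    net <- render_keypoints(generate_trial(spec))
    clean <- render_keypoints(generate_trial(
      trial_spec(jitter_sd_px = 0, outlier_rate = 0, seed = 40 + i)))
    res <- correct_track(net, displacement_flow(clean))
    subs <- length(res$report$wrist$substituted_frames) +
      length(res$report$elbow$substituted_frames)
    expect_lt(subs / (2 * net$n_frames), 0.01)
  }
})
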