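test_that("zero period variance gives exact 1-second half-cycles", {
  spec <- trial_spec(duration_s = 20, fps = 30, cycle_period_mean_s = 2,
                     cycle_period_sd_s = 0, angle_min_deg = 0,
                     angle_max_deg = 120, seed = 5)
  trial <- generate_trial(spec)
  expect_equal(trial$n_frames, 600L)
  expect_equal(length(trial$cycle_periods_s), 10L)
  expect_true(all(trial$phase_truth$duration_s == 1))
  expect_true(all(trial$cycle_periods_s == 2))
  # phases alternate and tile without overlap
  pt <- trial$phase_truth
  expect_true(all(pt$kind[-1] != pt$kind[-nrow(pt)]))
  expect_true(all(pt$start_frame[-1] == pt$end_frame[-nrow(pt)]))
  expect_equal(range(trial$theta_true), c(0, 120))
})

test_that("generation is deterministic in the seed", {
  spec <- trial_spec(seed = 7)
  t1 <- generate_trial(spec)
  t2 <- generate_trial(spec)
  expect_identical(t1$theta_true, t2$theta_true)
  expect_identical(t1$phase_truth, t2$phase_truth)
  expect_identical(render_keypoints(t1)$data, render_keypoints(t2)$data)
})

test_that("cycle period variability matches its sampling distribution", {
  durs <- unlist(lapply(1:200, function(i) {
    generate_trial(trial_spec(cycle_period_sd_s = 0.2, seed = i))$cycle_periods_s
  }))
  n <- length(durs)
  # sample SD of N(mu, 0.2) draws (frame quantisation adds ~1e-4 variance);
  # SE of the SD is approximately sd / sqrt(2 (n - 1))
  se <- 0.2 / sqrt(2 * (n - 1))
  expect_lt(abs(sd(durs) - 0.2), 3 * se + 0.01)
  expect_lt(abs(mean(durs) - 2), 0.05)
})

test_that("an impossible period specification errors", {
  spec <- trial_spec(cycle_period_mean_s = 0.1, cycle_period_sd_s = 0)
  expect_error(generate_trial(spec), "0.2 s")
})

test_that("noise-free keypoints reproduce the true angle exactly", {
  spec <- trial_spec(jitter_sd_px = 0, outlier_rate = 0, seed = 11)
  trial <- generate_trial(spec)
  track <- render_keypoints(trial)
  a <- compute_angle_sequence(track, variant = "synthetic")
  expect_lt(max(abs(a$values - trial$theta_true)), 1e-9)
})

test_that("injected outlier count matches the Markov-chain expectation", {
  # Per frame, an outlier fires with probability p unless the previous
  # frame was an outlier. Independent oracle: the exact occupancy
  # recursion q_t = p (1 - q_(t-1)), q_1 = p.
  p <- 0.05
  n <- 600L
  q <- numeric(n)
  q[1] <- p
  for (t in 2:n) q[t] <- p * (1 - q[t - 1])
  expected <- sum(q)
  var_bound <- expected  # Bernoulli sum variance is at most the mean
  counts <- vapply(1:500, function(i) {
    tr <- render_keypoints(generate_trial(
      trial_spec(outlier_rate = p, seed = i)))
    sum(tr$data$wrist_outlier)
  }, numeric(1))
  se <- sqrt(var_bound / 500)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("outliers are never consecutive and distances stay plausible", {
  for (i in 1:20) {
    spec <- trial_spec(jitter_sd_px = 1.5, outlier_rate = 0.1,
                       outlier_magnitude_px = 60, seed = i)
    tr <- render_keypoints(generate_trial(spec))
    out <- which(tr$data$wrist_outlier)
    if (length(out) > 1) expect_true(all(diff(out) > 1))
    d <- tr$data
    len <- sqrt((d$wrist_x - d$elbow_x)^2 + (d$wrist_y - d$elbow_y)^2)
    clean <- !d$wrist_outlier
    # jitter on both joints: allow 4 sd per joint on the radial distance
    expect_true(all(abs(len[clean] - spec$forearm_len) <=
                      4 * 2 * spec$jitter_sd_px))
  }
})

test_that("rendered frames are deterministic, local and peak at keypoints", {
  spec <- trial_spec(elbow_anchor = c(30, 34), forearm_len = 20,
                     jitter_sd_px = 0, seed = 2)
  trial <- generate_trial(spec)
  track <- render_keypoints(trial)
  short <- new_short_track(track, 3L)
  fr <- render_frames(short, size = 64)
  fr2 <- render_frames(short, size = 64)
  expect_identical(fr, fr2)

  # static track renders bit-identical frames
  static <- short
  static$data$wrist_x[] <- static$data$wrist_x[1]
  static$data$wrist_y[] <- static$data$wrist_y[1]
  static$data$elbow_x[] <- static$data$elbow_x[1]
  static$data$elbow_y[] <- static$data$elbow_y[1]
  fs <- render_frames(static, size = 64)
  expect_identical(fs[[1]], fs[[2]])
  expect_identical(fs[[1]], fs[[3]])

  # intensity argmax within 1 px of the wrist blob (brute-force argmax)
  f1 <- fr[[1]]
  d <- short$data
  # mask out the elbow blob neighbourhood, then argmax = wrist
  m <- f1
  er <- round(d$elbow_y[1]) + 1
  ec <- round(d$elbow_x[1]) + 1
  m[max(1, er - 6):min(64, er + 6), max(1, ec - 6):min(64, ec + 6)] <- -Inf
  k <- which(m == max(m), arr.ind = TRUE)[1, ]
  expect_lte(abs((k["col"] - 1) - d$wrist_x[1]), 1)
  expect_lte(abs((k["row"] - 1) - d$wrist_y[1]), 1)

  # moving the wrist changes the frame only near the wrist blob
  moved <- static
  moved$data$wrist_x <- moved$data$wrist_x + 1
  fm <- render_frames(moved, size = 64)
  dif <- abs(fm[[1]] - fs[[1]])
  nz <- which(dif > 1e-6, arr.ind = TRUE)
  wr <- round(d$wrist_y[1]) + 1
  wc <- round(d$wrist_x[1]) + 1
  expect_true(all(abs(nz[, "row"] - wr) <= 12 & abs(nz[, "col"] - wc) <= 13))

  # keypoints outside bounds error with the frame index
  off <- short
  off$data$wrist_x[2] <- 200
  expect_error(render_frames(off, size = 64), "frame 1")
})

test_that("cohort generation honours shapes, signs and determinism", {
  spec <- cohort_spec(n_subjects = 20, seed = 3)
  co <- generate_cohort(spec)
  expect_equal(nrow(co), 20L)
  expect_true(all(paste0("metric_", 1:6) %in% names(co)))
  expect_true(all(c("age", "sex", "bmi", "mmse", "tug") %in% names(co)))
  expect_true(all(co$mmse >= 0 & co$mmse <= 30))
  expect_true(all(co$tug >= 3))
  expect_identical(generate_cohort(spec), co)

  # zero noise and no clipping: outcomes are exactly linear in features
  s0 <- cohort_spec(noise_sd = c(0, 0), weight_scale = 0.1, seed = 9)
  c0 <- generate_cohort(s0)
  X <- dtuemp_predictors(c0)
  expect_equal(nrow(attr(c0, "clipped")), 0L)
  expect_equal(c0$mmse, 25.75 - drop(X %*% attr(c0, "w_mmse")),
               tolerance = 1e-12)
  expect_equal(c0$tug, 11.42 + drop(X %*% attr(c0, "w_tug")),
               tolerance = 1e-12)
})

test_that("support features correlate negatively with MMSE, positively with TUG", {
  signs_m <- numeric(0)
  signs_t <- numeric(0)
  for (i in 1:200) {
    co <- generate_cohort(cohort_spec(seed = i))
    X <- dtuemp_predictors(co)
    for (j in attr(co, "support")) {
      signs_m <- c(signs_m, cor(X[, j], co$mmse))
      signs_t <- c(signs_t, cor(X[, j], co$tug))
    }
  }
  expect_gt(mean(signs_m < 0), 0.95)
  expect_gt(mean(signs_t > 0), 0.95)
})
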