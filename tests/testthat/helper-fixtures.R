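# Shared fixtures and independent oracles. Oracles are deliberately
# brute-force and independent of the package's implementation paths.

# Smooth random texture with a known integer shift: returns frames f1, f2
# where the content of f2 is f1 displaced by (dx, dy) pixels.
shifted_texture <- function(seed, dx, dy, size = 64, sigma = 2) {
  set.seed(seed)
  pad <- 4L
  big <- matrix(runif((size + 2 * pad)^2), size + 2 * pad, size + 2 * pad)
  sm <- dtuemp:::smooth2d(big, sigma)
  i0 <- pad + 1L
  f1 <- sm[i0:(i0 + size - 1L), i0:(i0 + size - 1L)]
  f2 <- sm[(i0 - dy):(i0 + size - 1L - dy), (i0 - dx):(i0 + size - 1L - dx)]
  list(f1 = f1, f2 = f2, dx = dx, dy = dy)
}

# First n frames of a track.
new_short_track <- function(track, n) {
  track$data <- track$data[seq_len(n), , drop = FALSE]
  track$n_frames <- n
  track
}

# Noisy-track fixture with isolated wrist outliers plus the exact flow of
# the noise-free geometry (same trial shape, rendered without noise).
outlier_fixture <- function(seed, outlier_rate = 0.05, jitter = 1,
                            magnitude = 80) {
  spec <- trial_spec(jitter_sd_px = jitter, outlier_rate = outlier_rate,
                     outlier_magnitude_px = magnitude, seed = seed)
  trial <- generate_trial(spec)
  net <- render_keypoints(trial)
  clean_spec <- trial_spec(jitter_sd_px = 0, outlier_rate = 0, seed = seed)
  clean <- render_keypoints(generate_trial(clean_spec))
  list(trial = trial, network = net, flow = displacement_flow(clean))
}

# Independent single-task lasso oracle: cyclic coordinate descent run to a
# tight tolerance on the objective ||Xw - y||^2 + rho1 |w|_1 + rhoL2 |w|^2.
cd_lasso <- function(X, y, rho1, rhoL2 = 0, tol = 1e-14, max_sweeps = 50000) {
  p <- ncol(X)
  w <- rep(0, p)
  xtx <- colSums(X^2)
  obj <- function(w) {
    sum((X %*% w - y)^2) + rho1 * sum(abs(w)) + rhoL2 * sum(w^2)
  }
  f_old <- obj(w)
  for (s in seq_len(max_sweeps)) {
    for (j in seq_len(p)) {
      r_j <- y - X[, -j, drop = FALSE] %*% w[-j]
      z <- 2 * sum(X[, j] * r_j)
      w[j] <- sign(z) * max(0, abs(z) - rho1) / (2 * xtx[j] + 2 * rhoL2)
    }
    f_new <- obj(w)
    if (abs(f_old - f_new) < tol * max(1, abs(f_old))) break
    f_old <- f_new
  }
  list(w = w, objective = obj(w))
}

# Multi-task objective value of a weight matrix on centred/standardized
# data (matches the mtl_lasso parameterisation).
mtl_objective <- function(W, Xs, Yc, rho1, rhoL2) {
  f <- rho1 * sum(abs(W)) + rhoL2 * sum(W^2)
  for (i in seq_len(ncol(W))) {
    f <- f + sum((Xs[[i]] %*% W[, i] - Yc[[i]])^2)
  }
  f
}

# Standardize-and-centre helper mirroring the fit's preprocessing, for
# oracle computations.
prep_task <- function(X, y) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  list(Xs = Xs, yc = y - mean(y))
}
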