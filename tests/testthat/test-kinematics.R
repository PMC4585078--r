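test_that("knee triangulation returns the anterior circle intersection", {
  # collinear, fully extended
  expect_lt(max(abs(triangulate_knee(c(0, 0), c(0.21, 0), 0.10, 0.11) -
                      c(0.10, 0))), 1e-8)
  # hip above ankle: closed form t = (d^2 + r1^2 - r2^2)/(2d), h = sqrt(r1^2 - t^2)
  k <- triangulate_knee(c(0, 0), c(0, -0.15), 0.10, 0.11)
  t <- (0.15^2 + 0.10^2 - 0.11^2) / (2 * 0.15)
  expect_equal(k, c(sqrt(0.10^2 - t^2), -t), tolerance = 1e-12)
  expect_equal(k, c(0.07332, -0.0680), tolerance = 1e-4)
  # out of reach
  expect_error(triangulate_knee(c(0, 0), c(0.22, 0), 0.10, 0.11),
               "reachable annulus")
  # marginal overreach clamps to the collinear solution
  k2 <- triangulate_knee(c(0, 0), c(0.21 + 5e-7, 0), 0.10, 0.11)
  expect_lt(max(abs(k2 - c(0.10, 0))), 1e-5)
  # matrix input, one row per frame
  km <- triangulate_knee(rbind(c(0, 0), c(0, 0)),
                         rbind(c(0, -0.15), c(0.21, 0)), 0.10, 0.11)
  expect_equal(dim(km), c(2, 2))
  expect_lt(max(abs(km[2, ] - c(0.10, 0))), 1e-8)
})

test_that("segment angles are recovered exactly from noiseless markers", {
  leg <- default_leg()
  coh <- noiseless_cohort()
  tr <- coh$trials[[2]]
  truth <- coh$truth[[2]]$trajectory
  th <- segment_angles(tr, leg)
  # compare at the capture frames against the generator's 1-ms truth
  idx <- round(tr$t / 0.001) + 1
  idx <- pmin(idx, nrow(truth$theta))
  expect_lt(max(abs(th - truth$theta[idx, ])), 1e-6)
})

test_that("zero-phase Butterworth preserves DC and halves power at cutoff", {
  fs <- 60
  x <- rep(3.7, 120)
  expect_equal(zero_phase_butter(x, fs, 10), x, tolerance = 1e-9)
  t <- seq(0, 10, by = 1 / fs)
  low <- sin(2 * pi * 2 * t)
  yl <- zero_phase_butter(low, fs, 10)
  mid <- 121:480  # an integer number of cycles away from the ends
  amp <- function(y) sqrt(2 * mean(y^2))
  expect_equal(amp(yl[mid]), 1, tolerance = 0.01)
  hi <- sin(2 * pi * 10 * t)
  yh <- zero_phase_butter(hi, fs, 10)
  # -3 dB applied twice by the forward-backward pass
  expect_equal(amp(yh[mid]), 0.5, tolerance = 0.02)
  expect_error(zero_phase_butter(x, 60, 40), "Nyquist")
})

test_that("filter_and_resample yields a 1-ms grid through a cubic spline", {
  fs <- 60
  x <- sin(2 * pi * 1.5 * (0:90) / fs)
  out <- filter_and_resample(x, fs)
  expect_equal(diff(out$t)[1], 0.001)
  expect_equal(length(out$t), length(out$y))
  expect_lt(max(abs(out$y - sin(2 * pi * 1.5 * out$t))), 0.01)
  expect_error(filter_and_resample(x[1:10], fs), "0.5 s")
})

test_that("forward first-differences differentiate ramps exactly", {
  dt <- 0.001
  t <- seq(0, 1, by = dt)
  expect_equal(differentiate(3 * t, dt), rep(3, length(t)))
  expect_equal(differentiate(rep(2, 100), dt), rep(0, 100))
  s <- sin(2 * pi * 5 * t)
  d <- differentiate(s, dt)
  err <- abs(d - 2 * pi * 5 * cos(2 * pi * 5 * t))
  # first-difference truncation bound, away from the repeated last sample
  expect_lt(max(err[-length(err)]), (2 * pi * 5)^2 * dt / 2)
  expect_error(differentiate(1, dt), "2 samples")
})

test_that("swing onset detection follows the rise-and-persist rule", {
  dt <- 0.001
  expect_error(detect_swing_onset(rep(0, 1000), dt), "no swing onset")
  # flat for 200 ms then a 0.1 m/s ramp: reported at the 5-mm crossing
  y <- c(rep(0, 200), 0.1 * dt * seq_len(600))
  expect_equal(detect_swing_onset(y, dt), 250, tolerance = 1)
  # a blip shorter than the persistence window is ignored
  y2 <- rep(0, 1000)
  y2[300:320] <- 0.01
  expect_error(detect_swing_onset(y2, dt), "no swing onset")
  # onset on a noiseless synthetic trial lands near the command onset
  truth <- noiseless_cohort()$truth[[1]]
  expect_lt(abs(truth$onset_time - truth$command_onset), 0.120)
})

test_that("toe slope divides 2 cm of rise by the horizontal progress", {
  # 45-degree line
  x <- seq(0, 0.1, by = 1e-3)
  expect_equal(as.numeric(toe_trajectory_slope(cbind(x, x))), 1,
               tolerance = 1e-9)
  # vertical rise with a 1-cm drift between the heights
  y <- seq(0, 0.1, by = 1e-3)
  x2 <- 0.5 * y  # dx = 0.01 m between 3 and 5 cm
  expect_equal(as.numeric(toe_trajectory_slope(cbind(x2, y))), 2,
               tolerance = 1e-9)
  # parabola y = x^2 / 0.1, slope = 0.02 / (sqrt(0.005) - sqrt(0.003))
  xp <- seq(0, 0.12, by = 1e-5)
  expect_equal(as.numeric(toe_trajectory_slope(cbind(xp, xp^2 / 0.1))),
               0.02 / (sqrt(0.005) - sqrt(0.003)), tolerance = 1e-3)
  # never reaches 5 cm
  expect_error(toe_trajectory_slope(cbind(x, x * 0.3)), "never rises")
  # backward motion is returned negative and flagged
  xb <- seq(0.1, 0, by = -1e-3)
  yb <- seq(0, 0.1, by = 1e-3)
  expect_warning(sb <- toe_trajectory_slope(cbind(xb, yb)), "backward")
  expect_lt(as.numeric(sb), 0)
})

test_that("slope is invariant to translation and time reparameterisation", {
  xp <- seq(0, 0.12, by = 1e-4)
  path <- cbind(xp, xp^2 / 0.1)
  s0 <- as.numeric(toe_trajectory_slope(path))
  shifted <- sweep(path, 2, c(1.3, 0), `+`)
  expect_equal(as.numeric(toe_trajectory_slope(shifted)), s0,
               tolerance = 1e-6)
  # resample the same geometric path non-uniformly
  u <- sort(stats::runif(3000))^2 * 0.12
  expect_equal(as.numeric(toe_trajectory_slope(cbind(u, u^2 / 0.1))), s0,
               tolerance = 1e-3)
})

test_that("initial toe-to-barrier distance is measured at swing onset", {
  path <- cbind(seq(0, 0.3, length.out = 100), 0)
  expect_equal(initial_toe_to_barrier_distance(0.20, path, 1L), 0.20)
  expect_equal(initial_toe_to_barrier_distance(0.20,
                                               cbind(0.20, 0), 1L), 0)
  coh <- noiseless_cohort()
  leg <- default_leg()
  f <- fitted_clean_trial()
  # the toe sweeps back slightly before lifting (no stance contact in the
  # model), so the distance at detected onset sits within ~1.5 cm of the
  # standing distance
  expect_equal(f$metrics$distance, coh$truth[[1]]$distance,
               tolerance = 0.08)
})

test_that("the marker pipeline recovers band-limited angle trajectories", {
  # markers synthesized from slow (< 2 Hz) angle motion at 60 Hz:
  # angle extraction + filtering + resampling must recover the signal
  leg <- default_leg()
  fs <- 60
  tt <- (0:120) / fs
  th_fun <- function(t) cbind(-1.2 + 0.15 * sin(2 * pi * 1.2 * t),
                              -2.1 + 0.10 * cos(2 * pi * 0.8 * t),
                              -1.1 + 0.08 * sin(2 * pi * 1.5 * t),
                              -0.1 + 0.05 * cos(2 * pi * 1.0 * t))
  th60 <- th_fun(tt)
  L <- leg$segments$length
  mk_from <- function(k) t(sapply(seq_along(tt), function(i)
    colSums(L[seq_len(k), drop = FALSE] *
              cbind(cos(th60[i, seq_len(k)]), sin(th60[i, seq_len(k)])))))
  mk <- list(iliac_crest = mk_from(1) * 0 + rep(c(-0.05, 0.03), each = length(tt)),
             hip = mk_from(1) * 0,
             ankle = mk_from(2), paw_joint = mk_from(3), toe = mk_from(4))
  tr <- leg_trial("slow", tt, mk, sample_rate = fs)
  th_raw <- segment_angles(tr, leg)
  expect_lt(max(abs(th_raw - th60)), 1e-9)
  out <- apply(th_raw, 2, filter_and_resample, fs = fs, simplify = FALSE)
  th_ms <- sapply(out, `[[`, "y")
  expect_lt(max(abs(th_ms - th_fun(out[[1]]$t))), 0.01)
})

test_that("processed trajectories expose both toe paths on a 1-ms grid", {
  leg <- default_leg()
  coh <- noiseless_cohort()
  traj <- process_trial(coh$trials[[3]], leg)
  expect_equal(traj$t[2] - traj$t[1], 0.001)
  # velocities consistent with finite differences of the angles
  v_fd <- apply(traj$theta, 2, differentiate_centered, dt = 0.001)
  expect_equal(traj$theta_dot, v_fd, tolerance = 1e-12)
  # the marker-based toe path tracks the angle-based one to a few mm
  expect_lt(stats::median(abs(traj$toe_path - traj$toe_path_marker)), 0.005)
})
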