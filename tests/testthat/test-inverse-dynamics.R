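make_static_traj <- function(theta, n = 400, onset = 1L) {
  th <- matrix(theta, n, 4, byrow = TRUE)
  z <- matrix(0, n, 4)
  leg <- default_leg()
  toe <- matrix(joint_and_com_positions(leg, theta)$joints["toe", ],
                n, 2, byrow = TRUE)
  kinematic_trajectory((0:(n - 1)) * 0.001, th, z, z, toe,
                       swing_onset_index = onset)
}

test_that("trajectory torques reduce to the static oracle for held postures", {
  leg <- default_leg()
  hang <- solve_trial_torques(leg, make_static_traj(rep(-pi / 2, 4)))
  expect_lt(max(abs(hang$tau)), 1e-10)
  flat <- solve_trial_torques(leg, make_static_traj(rep(0, 4)))
  expect_equal(unname(flat$tau[1, "knee"]),
               9.81 * (0.1 * 0.055 + 0.04 * 0.135 + 0.02 * 0.17),
               tolerance = 1e-10)
  expect_equal(dim(flat$forces), c(400, 8))
  # profile is re-timed from the onset sample
  shifted <- solve_trial_torques(leg, make_static_traj(rep(0, 4),
                                                       onset = 101L))
  expect_equal(length(shifted$t), 300)
  expect_equal(shifted$t[1], 0)
})

test_that("forward-simulated motion returns its driving torques", {
  leg <- default_leg()
  spec <- cohort_spec(n_trials = 1, marker_noise_sd = 0)
  prof <- make_torque_profile(spec, 0.15, leg)
  st <- make_initial_state(leg, 0.15)
  sim <- simulate_swing(leg, st$theta, st$theta_dot, prof)
  # differentiate the simulated angles the way the pipeline does
  thd <- apply(sim$theta, 2, differentiate_centered, dt = 0.001)
  thdd <- apply(thd, 2, differentiate_centered, dt = 0.001)
  traj <- kinematic_trajectory(sim$t, sim$theta, thd, thdd, sim$toe_path)
  rec <- solve_trial_torques(leg, traj)
  keep <- 2:300
  rms <- sqrt(colMeans((rec$tau[keep, ] - prof$tau[keep, ])^2))
  peak <- apply(abs(prof$tau), 2, max)
  expect_lt(max(rms / peak), 0.01)
})

test_that("profile averaging is a truncated sample-wise mean", {
  t <- seq(0, 0.25, by = 0.001)
  p1 <- torque_profile(t, matrix(1, length(t), 4))
  p3 <- torque_profile(t, matrix(3, length(t), 4))
  avg <- average_torque_profiles(list(p1, p3))
  expect_equal(unique(as.vector(avg$tau)), 2)
  expect_equal(length(avg$t), 201)
  expect_equal(average_torque_profiles(list(p1, p1))$tau,
               p1$tau[1:201, ])
  # short profiles are dropped with a warning
  short <- torque_profile(seq(0, 0.1, by = 0.001), matrix(9, 101, 4))
  expect_warning(avg2 <- average_torque_profiles(list(p1, short)),
                 "excluded")
  expect_equal(unique(as.vector(avg2$tau)), 1)
  expect_error(average_torque_profiles(list()), "no torque profiles")
  expect_error(suppressWarnings(average_torque_profiles(list(short))),
               "long enough")
})

test_that("initial torques average the first 30 ms from swing onset", {
  t <- seq(0, 0.2, by = 0.001)
  const <- torque_profile(t, matrix(rep(c(1, -2, 3, 4), each = length(t)),
                                    ncol = 4))
  it <- initial_torques(const)
  expect_equal(unname(it$tau0), c(1, -2, 3, 4))
  expect_equal(it$window, 0.030)
  # linear knee ramp 0 -> -0.3 N m over 30 ms: mean -0.15
  tau <- matrix(0, length(t), 4)
  tau[, 2] <- pmax(-0.3, -0.3 * t / 0.03)
  ramp <- initial_torques(torque_profile(t, tau))
  expect_equal(unname(ramp$tau0[2]), -0.15, tolerance = 0.01)
  expect_error(initial_torques(const, window = -1), "> 0")
  expect_error(initial_torques(torque_profile(t[1:10],
                                              matrix(0, 10, 4))),
               "shorter")
})

test_that("torque profiles round-trip through CSV", {
  leg <- default_leg()
  prof <- solve_trial_torques(leg, make_static_traj(rep(0, 4), n = 60))
  path <- tempfile(fileext = ".csv")
  write_torque_profile(prof, path)
  back <- read_torque_profile(path)
  expect_equal(back$tau, prof$tau, tolerance = 1e-6)
  expect_equal(back$forces, prof$forces, tolerance = 1e-6)
  expect_equal(back$t, prof$t, tolerance = 1e-9)
})

test_that("swing_fit behaves like a model object", {
  f <- fitted_clean_trial()
  expect_s3_class(f, "swing_fit")
  expect_named(coef(f), c("hip", "knee", "ankle", "paw"))
  expect_output(print(f), "toe-trajectory slope")
  expect_output(print(summary(f)), "torque ranges")
  sim <- simulate(f, duration = 0.2)
  expect_s3_class(sim, "kinematic_trajectory")
  r <- residuals(f, duration = 0.2)
  expect_equal(dim(r), c(201, 2))
  # the re-simulated toe path shadows the observed one (model verification)
  expect_lt(max(abs(r)), 1e-3)
})
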