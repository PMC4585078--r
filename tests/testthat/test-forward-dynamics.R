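test_that("a hanging leg with zero torques is a fixed point", {
  leg <- default_leg()
  sim <- simulate_swing(leg, rep(-pi / 2, 4), rep(0, 4), rep(0, 4),
                        duration = 1)
  expect_lt(max(abs(sweep(sim$theta, 2, rep(-pi / 2, 4)))), 1e-9)
  expect_lt(max(abs(sim$theta_dot)), 1e-9)
})

test_that("forward accelerations invert inverse-dynamics torques", {
  leg <- default_leg()
  th <- c(-1.9, -2.2, -1.2, -0.1)
  thd <- c(3, -1, 2, 0.5)
  thdd_star <- c(25, -40, 60, -10)
  tau <- inverse_dynamics_state(leg, th, thd, thdd_star)$tau
  expect_equal(angular_accelerations(leg, th, thd, tau)$theta_ddot,
               thdd_star, tolerance = 1e-9)
  # equilibrium: hanging leg, zero torques
  acc <- angular_accelerations(leg, rep(-pi / 2, 4), rep(0, 4), rep(0, 4))
  expect_lt(max(abs(acc$theta_ddot)), 1e-12)
})

test_that("the single-rod limit behaves as a uniform-rod pendulum", {
  # distal masses scaled to 1e-9 of the default: thigh dynamics decouple
  leg <- leg_model(masses = c(0.2, 1e-9 * c(0.1, 0.04, 0.02)))
  L <- 0.10
  phi <- 0.05
  acc <- angular_accelerations(leg, rep(-pi / 2 + phi, 4), rep(0, 4),
                               rep(0, 4))
  expect_equal(acc$theta_ddot[1], -(3 * leg$g / (2 * L)) * sin(phi),
               tolerance = 1e-4)
  # small-oscillation period 2 pi sqrt(2L / 3g) = 0.518 s
  sim <- simulate_swing(leg, rep(-pi / 2 + phi, 4), rep(0, 4), rep(0, 4),
                        duration = 1.2)
  x <- sim$theta[, 1] + pi / 2
  crossings <- which(diff(sign(x)) != 0)
  period <- 2 * mean(diff(sim$t[crossings]))
  expect_equal(period, 2 * pi * sqrt(2 * L / (3 * leg$g)), tolerance = 0.01)
  expect_equal(period, 0.518, tolerance = 0.01)
})

test_that("torque-free motion conserves mechanical energy at dt = 1 ms", {
  leg <- default_leg()
  th0 <- c(-1.2, -2.4, -1.0, -0.3)
  sim <- simulate_swing(leg, th0, rep(0, 4), rep(0, 4), duration = 0.5)
  E <- vapply(seq_along(sim$t), function(k)
    mechanical_energy(leg, sim$theta[k, ], sim$theta_dot[k, ]), numeric(1))
  ke_peak <- max(vapply(seq_along(sim$t), function(k)
    mechanical_energy(leg, sim$theta[k, ], sim$theta_dot[k, ]) -
      mechanical_energy(leg, sim$theta[k, ], rep(0, 4)), numeric(1)))
  expect_lt(max(abs(E - E[1])) / ke_peak, 0.001)
})

test_that("halving the step barely moves the 200-ms toe position", {
  leg <- default_leg()
  th0 <- c(-1.2, -2.4, -1.0, -0.3)
  s1 <- simulate_swing(leg, th0, rep(0, 4), rep(0, 4),
                       dt = 0.001, duration = 0.2)
  s2 <- simulate_swing(leg, th0, rep(0, 4), rep(0, 4),
                       dt = 0.0005, duration = 0.2)
  d <- sqrt(sum((s1$toe_path[nrow(s1$toe_path), ] -
                   s2$toe_path[nrow(s2$toe_path), ])^2))
  expect_lt(d, 1e-6)
})

test_that("torque profiles drive the simulation with zero-order hold", {
  leg <- default_leg()
  prof <- torque_profile(seq(0, 0.1, by = 0.001),
                         matrix(0, 101, 4))
  sim <- simulate_swing(leg, rep(-pi / 2, 4), rep(0, 4), prof)
  expect_equal(length(sim$t), 101)  # duration taken from the profile
  # constant vector and function sources agree
  s1 <- simulate_swing(leg, rep(-1, 4), rep(0, 4), c(0.1, 0, 0, 0),
                       duration = 0.05)
  s2 <- simulate_swing(leg, rep(-1, 4), rep(0, 4),
                       function(t) c(0.1, 0, 0, 0), duration = 0.05)
  expect_equal(s1$theta, s2$theta)
})

test_that("runaway simulations stop with a divergence error", {
  leg <- leg_model(masses = c(0.2, 0.1, 0.04, 1e-6))
  expect_error(
    simulate_swing(leg, c(-1.2, -2.0, -1.0, -0.5), rep(0, 4),
                   c(0, 0, 0, 0.5), duration = 1),
    "diverged at step")
})

test_that("fixed-command simulations order slopes by initial flexion", {
  leg <- default_leg()
  spec <- cohort_spec(n_trials = 1, marker_noise_sd = 0)
  prof <- make_torque_profile(spec, 0.25, leg)
  geoms <- lapply(c(0.07, 0.24), function(d) {
    st <- make_initial_state(leg, d)
    list(theta = st$theta, hip = st$hip, ground_y = 0)
  })
  res <- run_fixed_command_experiment(leg, prof, rep(0, 4), geoms,
                                      barrier_x = leg$barrier_x)
  # nearer (more flexed) start rises more steeply under the same command
  expect_gt(res$simulated_slope[1], res$simulated_slope[2])
  expect_equal(res$distance, c(0.07, 0.24), tolerance = 1e-6)
  # identical geometries give identical slopes
  res2 <- run_fixed_command_experiment(leg, prof, rep(0, 4),
                                       geoms[c(1, 1)], leg$barrier_x)
  expect_equal(res2$simulated_slope[1], res2$simulated_slope[2])
})
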