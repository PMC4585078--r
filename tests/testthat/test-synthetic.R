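test_that("cohort generation is bit-identical under one seed", {
  leg <- default_leg()
  spec <- cohort_spec(n_trials = 2, seed = 42)
  a <- generate_cohort(leg, spec)
  b <- generate_cohort(leg, spec)
  expect_identical(a$trials, b$trials)
  expect_identical(a$truth[[1]]$tau0, b$truth[[1]]$tau0)
  spec2 <- cohort_spec(n_trials = 2, seed = 43)
  c2 <- generate_cohort(leg, spec2)
  expect_false(identical(a$trials[[1]]$markers$toe, c2$trials[[1]]$markers$toe))
  expect_false(isTRUE(all.equal(a$trials[[1]]$meta$distance,
                                c2$trials[[1]]$meta$distance)))
})

test_that("cohort distances are uniform over the requested range", {
  leg <- default_leg()
  spec <- cohort_spec(n_trials = 50, seed = 8)
  set.seed(spec$seed)
  d_expect <- stats::runif(50, 0.05, 0.25)
  coh <- noiseless_cohort(n = 4, seed = 7)
  d4 <- vapply(coh$truth, `[[`, numeric(1), "distance")
  expect_true(all(d4 >= 0.05 & d4 <= 0.25))
  # mean within 3 SE of the midpoint for the larger draw
  se <- (0.25 - 0.05) / sqrt(12) / sqrt(50)
  expect_lt(abs(mean(d_expect) - 0.15), 3 * se)
})

test_that("initial states put the toe on the ground at the right distance", {
  leg <- default_leg()
  for (d in c(0.05, 0.12, 0.25)) {
    st <- make_initial_state(leg, d)
    pos <- joint_and_com_positions(leg, st$theta)
    toe_w <- st$hip + pos$joints["toe", ]
    expect_equal(unname(toe_w[2]), 0, tolerance = 1e-9)
    expect_equal(unname(leg$barrier_x - toe_w[1]), d, tolerance = 1e-9)
    expect_equal(st$theta_dot, rep(0, 4))
  }
  # knee interior angle shrinks monotonically as the start nears the barrier
  interior <- vapply(seq(0.05, 0.25, by = 0.05), function(d) {
    th <- make_initial_state(leg, d)$theta
    acos(-cos(th[1] - th[2]))
  }, numeric(1))
  expect_true(all(diff(interior) > 0))
  expect_error(make_initial_state(leg, 1.5), "unreachable")
})

test_that("torque pulses are linear in the modulation gain", {
  leg <- default_leg()
  spec0 <- cohort_spec(knee_modulation_gain = 0)
  p1 <- make_torque_profile(spec0, 0.06, leg)
  p2 <- make_torque_profile(spec0, 0.22, leg)
  expect_equal(p1$tau, p2$tau)  # gain 0: identical at all distances
  g <- -0.4
  specg <- cohort_spec(knee_modulation_gain = g)
  q1 <- make_torque_profile(specg, 0.10, leg)
  q2 <- make_torque_profile(specg, 0.20, leg)
  dknee <- q1$tau[, "knee"] - q2$tau[, "knee"]
  expect_equal(min(dknee), g * 0.10, tolerance = 1e-9)
  expect_equal(q1$tau[, "hip"], q2$tau[, "hip"])
  # at the maximum distance the knee pulse equals the base amplitude
  base <- make_torque_profile(spec0, 0.25, leg)
  qmax <- make_torque_profile(specg, 0.25, leg)
  expect_equal(qmax$tau, base$tau)
})

test_that("generated trials satisfy the trial schema and stand still first", {
  coh <- noiseless_cohort()
  tr <- coh$trials[[1]]
  expect_s3_class(tr, "leg_trial")
  expect_equal(tr$sample_rate, 60)
  expect_named(tr$markers, c("iliac_crest", "hip", "ankle", "paw_joint",
                             "toe"))
  expect_named(tr$emg, c("ST", "Sart_m", "IP"))
  # standing prefix: toe height constant at 0 for the first 300 ms
  stand <- tr$t < 0.3
  expect_lt(max(abs(tr$markers$toe[stand, 2])), 1e-6)
  # hip marker fixed at standing height
  expect_lt(max(abs(tr$markers$hip[, 2] - 0.23)), 1e-6)
  # noiseless pipeline recovers the true slope within 2 percent
  f <- fitted_clean_trial()
  expect_equal(f$metrics$slope, coh$truth[[1]]$slope, tolerance = 0.02)
})

test_that("zero gain and zero noise give distance-independent knee torques", {
  leg <- default_leg()
  spec <- cohort_spec(n_trials = 1, seed = 5, marker_noise_sd = 0,
                      knee_modulation_gain = 0)
  tau0 <- vapply(c(0.08, 0.22), function(d) {
    tr <- generate_trial(leg, spec, d)$trial
    fit_swing_dynamics(tr, leg)$metrics$tau0[["knee"]]
  }, numeric(1))
  # identical commands: any residual difference is filter-level, not the
  # 30 mN m the default modulation would produce over this distance gap
  expect_lt(abs(tau0[1] - tau0[2]), 0.005)
})
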