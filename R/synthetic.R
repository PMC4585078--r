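#' Synthetic cohort specification
#'
#' Parameters of the synthetic-trial generator.  A cohort emulates a
#' leading hind leg swinging over a remembered 6.5-cm barrier from initial
#' toe-to-barrier distances spanning 5-25 cm, with the knee flexion pulse
#' growing as the toe starts closer to the barrier (the neural-modulation
#' component) and hip/ankle/paw pulses independent of distance.
#'
#' During the standing prefix each trial is held by its own posture's
#' static torques; at command onset the torques step to a swing command
#' shared by all trials -- the reference-posture static hold plus smooth
#' raised-cosine-edged flexion pulses -- except for the distance-modulated
#' knee pulse.  With \code{knee_modulation_gain = 0} every trial therefore
#' receives an identical swing-phase torque profile regardless of its
#' initial geometry, which is the purely-mechanical condition.
#'
#' @param n_trials number of trials.
#' @param distance_range range of initial toe-to-barrier distances, m.
#' @param knee_modulation_gain N m per m of proximity added to the knee
#'   pulse amplitude: amplitude(d) = base + gain * (d_max - d).  Negative
#'   (knee flexion is clockwise/negative for this leg orientation); 0
#'   disables neural modulation.  The default raises the knee pulse from
#'   -0.025 N m at the farthest start to -0.055 N m at the nearest.
#' @param base_amplitude numeric(4), pulse amplitudes at the farthest
#'   distance (hip, knee, ankle, paw), N m.
#' @param rise_time pulse rise/fall time, s.
#' @param pulse_duration total pulse duration per joint, s.
#' @param marker_noise_sd i.i.d. Gaussian marker noise per coordinate, m.
#' @param emg_noise_sd EMG noise-floor SD, AU.
#' @param emg_gain AU of EMG carrier amplitude per N m of the driving
#'   joint's pulse amplitude (channels ST, Sart_m: knee; IP: hip).
#' @param standing_duration static standing prefix, s.
#' @param profile_duration swing command duration, s.
#' @param emg_rate EMG sampling rate, Hz.
#' @param animals labels cycled over trials (pseudo-animals).
#' @param seed integer; fixes all randomness of the cohort.
#' @return list of class \code{"cohort_spec"}.
#' @export
cohort_spec <- function(n_trials = 50,
                        distance_range = c(0.05, 0.25),
                        knee_modulation_gain = -0.15,
                        base_amplitude = c(hip = 0.22, knee = -0.025,
                                           ankle = 0.005, paw = 0.0005),
                        rise_time = 0.050,
                        pulse_duration = 0.190,
                        marker_noise_sd = 5e-4,
                        emg_noise_sd = 0.05,
                        emg_gain = c(ST = 8, Sart_m = 6, IP = 5),
                        standing_duration = 0.300,
                        profile_duration = 0.340,
                        emg_rate = 1000,
                        animals = "A",
                        seed = 1L) {
  stopifnot(n_trials >= 1, length(distance_range) == 2,
            distance_range[1] > 0, distance_range[2] <= 0.4,
            distance_range[1] < distance_range[2],
            length(base_amplitude) == 4, rise_time > 0,
            pulse_duration > 2 * rise_time, marker_noise_sd >= 0,
            emg_noise_sd >= 0)
  structure(as.list(environment()), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Synthetic cohort spec: %d trial(s), distances %.0f-%.0f cm, seed %d\n",
              x$n_trials, 100 * x$distance_range[1],
              100 * x$distance_range[2], x$seed))
  cat(sprintf("  knee modulation gain %.2f N m/m, marker noise %.2g mm\n",
              x$knee_modulation_gain, 1000 * x$marker_noise_sd))
  invisible(x)
}

# standing posture family: thigh/paw/toe segment angles (deg) at the far
# and near anchor distances, hip standing height (m)
.posture_family <- list(
  d_far = 0.25, d_near = 0.05,
  far = c(thigh = -70, paw = -65, toe = -5),
  near = c(thigh = -60, paw = -72.5, toe = -10),
  hip_height = 0.23
)

#' Standing posture for a given toe-to-barrier distance
#'
#' Deterministic one-parameter posture family: the thigh, paw and toe
#' angles interpolate linearly between an extended far posture and a
#' flexed near posture (anchored at 25 and 5 cm), and the shank angle is
#' solved from the toe-on-ground constraint (hip fixed at standing height
#' 0.23 m).  Nearer distances give a more flexed knee and ankle, which is
#' the geometric regularity observed in stepping animals.
#'
#' @param leg a \code{\link{leg_model}}.
#' @param distance initial toe-to-barrier distance, m.
#' @param family posture-family parameters; see the package source for
#'   the default (anchor angles in degrees and standing hip height).
#' @return list of class \code{"leg_state"}: \code{theta} (rad),
#'   \code{theta_dot} (zeros), \code{hip} (world hip position: the hip x
#'   places the toe at \code{barrier_x - distance}), \code{distance}.
#' @export
make_initial_state <- function(leg, distance, family = .posture_family) {
  lam <- (family$d_far - distance) / (family$d_far - family$d_near)
  deg <- pi / 180
  th1 <- (family$far[1] + (family$near[1] - family$far[1]) * lam) * deg
  th3 <- (family$far[2] + (family$near[2] - family$far[2]) * lam) * deg
  th4 <- (family$far[3] + (family$near[3] - family$far[3]) * lam) * deg
  L <- leg$segments$length
  s2 <- (-family$hip_height - L[1] * sin(th1) - L[3] * sin(th3) -
           L[4] * sin(th4)) / L[2]
  if (abs(s2) > 1) stop(sprintf("unreachable posture at distance %.3f m",
                                distance))
  th2 <- -pi - asin(s2)
  theta <- unname(c(th1, th2, th3, th4))
  toe_rel_x <- sum(L * cos(theta))
  hip <- c(leg$barrier_x - distance - toe_rel_x, family$hip_height)
  structure(list(theta = theta, theta_dot = rep(0, 4), hip = hip,
                 distance = unname(distance)),
            class = "leg_state")
}

# raised-cosine-edged pulse shape on [0, dur], unit plateau
.pulse_shape <- function(t, rise, dur) {
  s <- numeric(length(t))
  up <- t >= 0 & t < rise
  flat <- t >= rise & t <= dur - rise
  down <- t > dur - rise & t <= dur
  s[up] <- 0.5 * (1 - cos(pi * t[up] / rise))
  s[flat] <- 1
  s[down] <- 0.5 * (1 - cos(pi * (dur - t[down]) / rise))
  s
}

#' Swing-command torque profile for one trial
#'
#' The applied joint torques from command onset (\code{t = 0}): a
#' postural holding component -- the static gravitational torques of the
#' \emph{reference} (most extended) posture, common to every trial -- plus
#' raised-cosine-edged flexion pulses at each joint.  Only the knee pulse
#' amplitude depends on distance, \code{base + gain * (d_max - d)}; with
#' \code{gain = 0} every trial receives the identical swing command.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param distance initial toe-to-barrier distance, m.
#' @param leg a \code{\link{leg_model}}.
#' @return a \code{\link{torque_profile}} of length
#'   \code{spec$profile_duration}.
#' @export
make_torque_profile <- function(spec, distance, leg = leg_model()) {
  stopifnot(inherits(spec, "cohort_spec"))
  amp <- spec$base_amplitude
  amp[2] <- amp[2] + spec$knee_modulation_gain *
    (spec$distance_range[2] - distance)
  static_ref <- static_joint_torques(
    leg, make_initial_state(leg, spec$distance_range[2])$theta)
  t <- seq(0, spec$profile_duration, by = 0.001)
  shape <- .pulse_shape(t, spec$rise_time, spec$pulse_duration)
  tau <- outer(shape, amp) + matrix(static_ref, length(t), 4, byrow = TRUE)
  torque_profile(t, tau)
}

#' Generate one synthetic trial
#'
#' Forward-simulates the swing under \code{\link{make_torque_profile}}
#' from \code{\link{make_initial_state}}, prepends a 300-ms static
#' standing segment (held by the posture's own static torques), samples
#' the markers at the capture rate with i.i.d. Gaussian noise, and
#' synthesises EMG channels (white-Gaussian carrier amplitude-modulated by
#' the driving joint's pulse, plus a noise floor).  Uses the current RNG
#' state; seed via \code{\link{generate_cohort}} or \code{set.seed}.
#'
#' @param leg a \code{\link{leg_model}}.
#' @param spec a \code{\link{cohort_spec}}.
#' @param distance initial toe-to-barrier distance, m.
#' @param trial_id label.
#' @param animal pseudo-animal label.
#' @return list with \code{trial} (a \code{\link{leg_trial}}) and
#'   \code{truth}: the generator's ground truth (\code{trajectory} at
#'   1 ms, \code{profile} = applied swing command, \code{command_onset}
#'   time s, \code{tau0} = plateau-level applied torques,
#'   \code{slope} = toe-trajectory slope of the noiseless trajectory,
#'   \code{emg_onset}, \code{emg_magnitude} = expected rectified-envelope
#'   integrals, \code{distance}).
#' @export
generate_trial <- function(leg, spec, distance, trial_id = "synth",
                           animal = "A") {
  state0 <- make_initial_state(leg, distance)
  profile <- make_torque_profile(spec, distance, leg)
  static_own <- static_joint_torques(leg, state0$theta)
  t_stand <- spec$standing_duration
  tau_fun <- function(t) {
    if (t < t_stand) static_own else zoh_torque(profile, t - t_stand)
  }
  leg_w <- leg
  leg_w$hip_origin <- state0$hip
  dur <- t_stand + spec$profile_duration
  sim <- simulate_swing(leg_w, state0$theta, state0$theta_dot, tau_fun,
                        dt = 0.001, duration = dur)

  # --- markers at the capture rate ---------------------------------------
  fs <- 60
  frame_t <- seq(0, dur, by = 1 / fs)
  idx <- round(frame_t / 0.001) + 1L
  idx <- pmin(idx, length(sim$t))
  L <- leg$segments$length
  joints_t <- function(k) {
    u <- cbind(cos(sim$theta[k, ]), sin(sim$theta[k, ]))
    pts <- rbind(c(0, 0), apply(L * u, 2, cumsum))
    sweep(pts, 2, state0$hip, `+`)
  }
  nfr <- length(idx)
  mk <- list(iliac_crest = matrix(NA_real_, nfr, 2),
             hip = matrix(NA_real_, nfr, 2), ankle = matrix(NA_real_, nfr, 2),
             paw_joint = matrix(NA_real_, nfr, 2),
             toe = matrix(NA_real_, nfr, 2))
  for (k in seq_len(nfr)) {
    pts <- joints_t(idx[k])
    mk$iliac_crest[k, ] <- pts[1, ] + c(-0.05, 0.03)
    mk$hip[k, ] <- pts[1, ]
    mk$ankle[k, ] <- pts[3, ]
    mk$paw_joint[k, ] <- pts[4, ]
    mk$toe[k, ] <- pts[5, ]
  }
  if (spec$marker_noise_sd > 0)
    mk <- lapply(mk, function(mm)
      mm + matrix(stats::rnorm(length(mm), 0, spec$marker_noise_sd),
                  nrow(mm)))

  # --- EMG ---------------------------------------------------------------
  amp_pulse <- spec$base_amplitude
  amp_pulse[2] <- amp_pulse[2] + spec$knee_modulation_gain *
    (spec$distance_range[2] - distance)
  drive_joint <- c(ST = 2L, Sart_m = 2L, IP = 1L)
  te <- seq(0, dur, by = 1 / spec$emg_rate)
  shape_e <- .pulse_shape(te - t_stand, spec$rise_time, spec$pulse_duration)
  emg <- list(); true_mag <- c()
  for (ch in names(spec$emg_gain)) {
    a_ch <- spec$emg_gain[[ch]] * abs(amp_pulse[drive_joint[[ch]]])
    env_true <- a_ch * shape_e
    v <- env_true * stats::rnorm(length(te)) +
      spec$emg_noise_sd * stats::rnorm(length(te))
    emg[[ch]] <- emg_trace(te, v, spec$emg_rate, channel = ch)
    # expected rectified mean of N(0, a^2 p^2 + sigma^2) integrated 150 ms
    win <- te >= t_stand & te <= t_stand + 0.150
    ev <- sqrt(2 / pi) * sqrt(env_true[win]^2 + spec$emg_noise_sd^2)
    true_mag[ch] <- (sum(ev) - (ev[1] + ev[sum(win)]) / 2) / spec$emg_rate
  }

  trial <- leg_trial(trial_id, frame_t, mk, sample_rate = fs,
                     barrier_x = leg$barrier_x, emg = emg,
                     meta = list(distance = distance, animal = animal))

  true_onset <- detect_swing_onset(sim$toe_path, dt = 0.001)
  true_slope <- tryCatch(
    as.numeric(toe_trajectory_slope(sim$toe_path, true_onset, ground_y = 0)),
    error = function(e) NA_real_)
  static_ref <- static_joint_torques(
    leg, make_initial_state(leg, spec$distance_range[2])$theta)
  truth <- list(trajectory = sim, profile = profile,
                command_onset = t_stand,
                tau0 = static_ref + amp_pulse,
                slope = true_slope,
                onset_time = sim$t[true_onset],
                emg_onset = t_stand,
                emg_magnitude = true_mag,
                distance = distance)
  list(trial = trial, truth = truth)
}

#' Generate a synthetic cohort
#'
#' Draws \code{n_trials} initial distances uniformly over the spec's
#' distance range under the spec's seed and generates one trial each
#' (round-robin over the pseudo-animal labels).  Fully reproducible:
#' the same spec yields bit-identical cohorts.
#'
#' @param leg a \code{\link{leg_model}}.
#' @param spec a \code{\link{cohort_spec}}.
#' @return list with \code{trials} (list of \code{\link{leg_trial}}) and
#'   \code{truth} (list of per-trial ground-truth records).
#' @export
generate_cohort <- function(leg, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  d <- stats::runif(spec$n_trials, spec$distance_range[1],
                    spec$distance_range[2])
  animals <- rep_len(spec$animals, spec$n_trials)
  out <- vector("list", spec$n_trials)
  for (i in seq_len(spec$n_trials))
    out[[i]] <- generate_trial(leg, spec, d[i],
                               trial_id = sprintf("synth_%03d", i),
                               animal = animals[i])
  list(trials = lapply(out, `[[`, "trial"),
       truth = lapply(out, `[[`, "truth"))
}
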