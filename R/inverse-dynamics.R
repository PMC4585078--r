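#' Joint torques for a whole trajectory
#'
#' Solves the inverse-mode 20-equation system at every sample of a
#' kinematic trajectory, returning joint torque and joint interaction
#' force time series.
#'
#' @param leg a \code{\link{leg_model}}.
#' @param traj a \code{\link{kinematic_trajectory}} with populated angular
#'   accelerations.
#' @param from_onset if TRUE (default) the returned profile starts at the
#'   trajectory's swing-onset sample, with \code{t = 0} there.
#' @return a \code{\link{torque_profile}} (torques and forces at the
#'   trajectory's resolution).
#' @export
solve_trial_torques <- function(leg, traj, from_onset = TRUE) {
  stopifnot(inherits(traj, "kinematic_trajectory"))
  idx <- if (from_onset) seq(traj$swing_onset_index, length(traj$t))
         else seq_along(traj$t)
  n <- length(idx)
  tau <- matrix(NA_real_, n, 4)
  forces <- matrix(NA_real_, n, 8)
  for (k in seq_len(n)) {
    i <- idx[k]
    sol <- tryCatch(
      inverse_dynamics_state(leg, traj$theta[i, ], traj$theta_dot[i, ],
                             traj$theta_ddot[i, ]),
      error = function(e)
        stop(sprintf("inverse dynamics failed at step %d: %s", i,
                     conditionMessage(e)), call. = FALSE))
    tau[k, ] <- sol$tau
    forces[k, ] <- c(sol$fx, sol$fy)
  }
  torque_profile(traj$t[idx] - traj$t[idx[1]], tau, forces)
}

#' Average torque profiles across trials
#'
#' Sample-wise mean of several torque profiles aligned at swing onset,
#' truncated to a common duration (200 ms by default, the window over
#' which averaged swing torques are analysed).  Profiles shorter than the
#' requested duration are excluded with a warning.
#'
#' @param profiles list of \code{\link{torque_profile}} objects.
#' @param duration common duration, s.
#' @return a \code{\link{torque_profile}}.
#' @export
average_torque_profiles <- function(profiles, duration = 0.200) {
  if (!length(profiles)) stop("no torque profiles to average")
  dt <- profiles[[1]]$t[2] - profiles[[1]]$t[1]
  n_out <- 1L + floor(duration / dt + 1e-9)
  long_enough <- vapply(profiles, function(p) length(p$t) >= n_out,
                        logical(1))
  if (!all(long_enough))
    warning(sprintf("%d profile(s) shorter than %.0f ms excluded from the average",
                    sum(!long_enough), 1000 * duration))
  profiles <- profiles[long_enough]
  if (!length(profiles)) stop("no profile is long enough to average")
  tau <- Reduce(`+`, lapply(profiles, function(p) p$tau[seq_len(n_out), ])) /
    length(profiles)
  have_forces <- all(vapply(profiles, function(p) !is.null(p$forces),
                            logical(1)))
  forces <- if (have_forces)
    Reduce(`+`, lapply(profiles, function(p) p$forces[seq_len(n_out), ])) /
      length(profiles)
  torque_profile((seq_len(n_out) - 1L) * dt, tau, forces)
}

#' Initial joint torques over the first 30 ms of swing
#'
#' Mean torque per joint over the window \code{[0, window]} from swing
#' onset -- the early-swing statistic whose knee component grows as the
#' toe starts closer to the barrier.
#'
#' @param profile a \code{\link{torque_profile}} aligned at swing onset.
#' @param window averaging window, s (default 30 ms).
#' @return list with \code{tau0} (named numeric(4): hip, knee, ankle, paw,
#'   N m) and \code{window}.
#' @export
initial_torques <- function(profile, window = 0.030) {
  if (!is.numeric(window) || window <= 0) stop("window must be > 0")
  dur <- profile$t[length(profile$t)] - profile$t[1]
  if (dur < window) stop("profile shorter than the averaging window")
  sel <- profile$t - profile$t[1] <= window + 1e-9
  list(tau0 = colMeans(profile$tau[sel, , drop = FALSE]), window = window)
}

#' Fit the four-link dynamics to a single trial
#'
#' The per-trial estimator: runs the motion-capture pipeline
#' (\code{\link{process_trial}}), solves the inverse dynamics for the
#' swing-phase joint torques, and computes the trial-level metrics
#' (initial toe-to-barrier distance, toe-trajectory slope, 30-ms initial
#' joint torques, and EMG burst magnitudes for any recorded channels).
#' The fitted object behaves like a classed model fit:
#' \code{coef()} returns the initial joint torques, \code{simulate()}
#' re-drives the forward model with the estimated torques,
#' \code{fitted()}/\code{residuals()} compare that simulation with the
#' observed toe path (the verification that the integration reproduces
#' the measured movement), and \code{plot()} draws stick figures and
#' torque profiles.
#'
#' @param trial a \code{\link{leg_trial}}.
#' @param leg a \code{\link{leg_model}} (defaults to the cat leg).
#' @param cutoff angle filter cutoff, Hz.
#' @param tau0_window initial-torque window, s.
#' @param emg_window EMG integration window, s.
#' @param knee_tol knee-triangulation tolerance, m.
#' @return object of class \code{"swing_fit"}: list with \code{trial},
#'   \code{leg}, \code{trajectory}, \code{torques} (swing-aligned
#'   \code{torque_profile}), and \code{metrics} (list: \code{distance},
#'   \code{slope}, \code{tau0}, \code{emg_magnitude},
#'   \code{onset_time}).
#' @export
fit_swing_dynamics <- function(trial, leg = leg_model(), cutoff = 10,
                               tau0_window = 0.030, emg_window = 0.150,
                               knee_tol = 2e-3) {
  traj <- process_trial(trial, leg, cutoff = cutoff, knee_tol = knee_tol)
  torques <- solve_trial_torques(leg, traj, from_onset = TRUE)
  toe_obs <- if (!is.null(traj$toe_path_marker)) traj$toe_path_marker
             else traj$toe_path
  slope <- toe_trajectory_slope(toe_obs, traj$swing_onset_index,
                                ground_y = traj$ground_y)
  distance <- if (is.finite(trial$barrier_x))
    initial_toe_to_barrier_distance(trial$barrier_x, toe_obs,
                                    traj$swing_onset_index)
  else NA_real_
  tau0 <- initial_torques(torques, tau0_window)$tau0
  emg_mag <- sapply(trial$emg, function(e) {
    tryCatch({
      env <- emg_envelope(e)
      onset <- detect_burst_onset(env, e$sample_rate)
      burst_magnitude(env, e$sample_rate, onset, emg_window)
    }, error = function(err) NA_real_)
  })
  structure(list(trial = trial, leg = leg, trajectory = traj,
                 torques = torques,
                 metrics = list(distance = distance,
                                slope = as.numeric(slope),
                                tau0 = tau0,
                                emg_magnitude = emg_mag,
                                onset_time = traj$t[traj$swing_onset_index])),
            class = "swing_fit")
}

#' @export
print.swing_fit <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("Four-link swing-dynamics fit of trial '%s'\n",
              x$trial$trial_id))
  cat(sprintf("  toe-to-barrier distance: %s\n",
              if (is.na(m$distance)) "unknown"
              else sprintf("%.1f cm", 100 * m$distance)))
  cat(sprintf("  toe-trajectory slope (3-5 cm): %.3f\n", m$slope))
  cat(sprintf("  initial torques (30 ms): hip %+.3f, knee %+.3f, ankle %+.3f N m\n",
              m$tau0[1], m$tau0[2], m$tau0[3]))
  if (length(m$emg_magnitude))
    cat(sprintf("  EMG burst magnitude [%s]: %s AU s\n",
                paste(names(m$emg_magnitude), collapse = ", "),
                paste(sprintf("%.3f", m$emg_magnitude), collapse = ", ")))
  invisible(x)
}

#' @export
coef.swing_fit <- function(object, ...) object$metrics$tau0

#' @export
summary.swing_fit <- function(object, ...) {
  out <- list(trial_id = object$trial$trial_id,
              metrics = object$metrics,
              torque_range = apply(object$torques$tau, 2, range),
              onset_index = object$trajectory$swing_onset_index,
              duration = diff(range(object$torques$t)))
  class(out) <- "summary.swing_fit"
  out
}

#' @export
print.summary.swing_fit <- function(x, ...) {
  cat(sprintf("Trial '%s': swing onset at sample %d, %0.f ms of swing analysed\n",
              x$trial_id, x$onset_index, 1000 * x$duration))
  cat(sprintf("  distance %.1f cm, slope %.3f\n",
              100 * x$metrics$distance, x$metrics$slope))
  cat("  torque ranges (N m):\n")
  for (j in colnames(x$torque_range))
    cat(sprintf("    %-5s [%+.3f, %+.3f]\n", j, x$torque_range[1, j],
                x$torque_range[2, j]))
  invisible(x)
}

#' Re-simulate a fitted trial with its estimated torques
#'
#' Drives the forward model from the trial's state at swing onset with the
#' torque profile estimated by the inverse dynamics -- the round-trip used
#' to verify that the numerical integration reproduces the observed
#' movement.
#'
#' @param object a \code{\link{fit_swing_dynamics}} fit.
#' @param nsim unused (the simulation is deterministic).
#' @param seed unused.
#' @param duration simulated time, s; defaults to the estimated profile's
#'   length.
#' @param ... passed to \code{\link{simulate_swing}}.
#' @return a \code{kinematic_trajectory} (world-frame toe path).
#' @export
simulate.swing_fit <- function(object, nsim = 1, seed = NULL,
                               duration = NULL, ...) {
  traj <- object$trajectory
  i0 <- traj$swing_onset_index
  leg <- object$leg
  leg$hip_origin <- traj$hip_origin
  simulate_swing(leg, traj$theta[i0, ], traj$theta_dot[i0, ],
                 torques = object$torques, duration = duration, ...)
}

#' @export
fitted.swing_fit <- function(object, duration = 0.200, ...) {
  simulate.swing_fit(object, duration = duration)$toe_path
}

#' @export
residuals.swing_fit <- function(object, duration = 0.200, ...) {
  sim <- fitted.swing_fit(object, duration = duration)
  i0 <- object$trajectory$swing_onset_index
  obs <- object$trajectory$toe_path[i0:(i0 + nrow(sim) - 1L), , drop = FALSE]
  obs - sim
}

#' Plot a swing-dynamics fit
#'
#' Left: observed (grey) and re-simulated (red) stick figures at 25-ms
#' intervals with the toe paths and the remembered barrier.  Right: the
#' estimated swing-phase joint torque profiles.
#'
#' @param x a \code{swing_fit}.
#' @param duration how much swing to draw, s.
#' @param ... unused.
#' @export
plot.swing_fit <- function(x, duration = 0.200, ...) {
  traj <- x$trajectory
  sim <- simulate.swing_fit(x, duration = duration)
  i0 <- traj$swing_onset_index
  leg <- x$leg
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  keep <- seq(1, nrow(sim$toe_path), by = 25)
  obs_idx <- i0 + keep - 1L
  stick <- function(theta_row, origin, col) {
    pts <- rbind(origin,
                 origin + t(apply(leg$segments$length *
                                    cbind(cos(theta_row), sin(theta_row)),
                                  2, cumsum)))
    graphics::lines(pts[, 1], pts[, 2], col = col)
  }
  rng_x <- range(traj$toe_path[obs_idx, 1], traj$hip_origin[1])
  rng_y <- range(traj$toe_path[obs_idx, 2], traj$hip_origin[2])
  graphics::plot(NA, xlim = rng_x + c(-0.05, 0.05),
                 ylim = rng_y + c(-0.02, 0.05), asp = 1,
                 xlab = "x (m)", ylab = "y (m)",
                 main = sprintf("trial '%s'", x$trial$trial_id))
  for (k in seq_along(keep)) {
    stick(traj$theta[obs_idx[k], ], traj$hip_origin, "grey60")
    stick(sim$theta[keep[k], ], traj$hip_origin, "indianred")
  }
  graphics::lines(traj$toe_path[obs_idx[1]:max(obs_idx), ], col = "grey30")
  graphics::lines(sim$toe_path, col = "red", lty = 2)
  if (is.finite(x$trial$barrier_x))
    graphics::rect(x$trial$barrier_x - 0.005, traj$ground_y,
                   x$trial$barrier_x + 0.005,
                   traj$ground_y + leg$barrier_height, border = "blue")
  graphics::matplot(x$torques$t * 1000, x$torques$tau, type = "l", lty = 1,
                    xlab = "time from swing onset (ms)",
                    ylab = "joint torque (N m)", main = "estimated torques")
  graphics::legend("topright", colnames(x$torques$tau), col = 1:4, lty = 1,
                   cex = 0.8)
  invisible(x)
}
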