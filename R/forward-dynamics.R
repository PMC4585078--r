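#' Joint-torque profile
#'
#' Time-aligned joint torques (and optionally joint interaction forces) at
#' 1-ms resolution, with \code{t = 0} at swing onset.  When a profile
#' drives a forward simulation its torques are zero-order-held between
#' samples.
#'
#' @param t time vector, s (uniform spacing).
#' @param tau n x 4 matrix of joint torques (hip, knee, ankle, paw), N m,
#'   anticlockwise-positive.
#' @param forces optional n x 8 matrix of joint interaction forces
#'   (fx hip..paw, fy hip..paw), N.
#' @return object of class \code{"torque_profile"}.
#' @export
torque_profile <- function(t, tau, forces = NULL) {
  tau <- as.matrix(tau)
  if (ncol(tau) != 4L) stop("tau must have 4 columns (hip, knee, ankle, paw)")
  if (length(t) != nrow(tau)) stop("t and tau lengths differ")
  if (any(!is.finite(tau))) stop("torques must be finite")
  colnames(tau) <- c("hip", "knee", "ankle", "paw")
  if (!is.null(forces)) {
    forces <- as.matrix(forces)
    if (nrow(forces) != length(t) || ncol(forces) != 8L)
      stop("forces must be an n x 8 matrix")
    colnames(forces) <- c(paste0("fx_", c("hip", "knee", "ankle", "paw")),
                          paste0("fy_", c("hip", "knee", "ankle", "paw")))
  }
  structure(list(t = as.numeric(t), tau = tau, forces = forces),
            class = "torque_profile")
}

#' @export
print.torque_profile <- function(x, ...) {
  cat(sprintf("Joint-torque profile: %d samples, %.0f ms, dt = %.1f ms\n",
              length(x$t), 1000 * (x$t[length(x$t)] - x$t[1]),
              1000 * stats::median(diff(x$t))))
  rng <- apply(x$tau, 2, range)
  cat(sprintf("  %-5s [%+.3f, %+.3f] N m\n", colnames(x$tau),
              rng[1, ], rng[2, ]), sep = "")
  invisible(x)
}

# zero-order-hold lookup of a torque profile at time t (s from profile start)
zoh_torque <- function(profile, t) {
  dt <- profile$t[2] - profile$t[1]
  k <- pmin(length(profile$t), pmax(1L, 1L + floor((t - profile$t[1]) / dt + 1e-9)))
  profile$tau[k, ]
}

#' Write / read torque profiles as CSV
#'
#' Column layout: \code{t_ms, tau_hip, tau_knee, tau_ankle, tau_paw} and,
#' if present, \code{fx_hip, ..., fy_paw}.
#' @param profile a \code{torque_profile}.
#' @param path file path.
#' @return \code{read_torque_profile} returns a \code{torque_profile}.
#' @export
write_torque_profile <- function(profile, path) {
  df <- data.frame(t_ms = profile$t * 1000,
                   tau_hip = profile$tau[, 1], tau_knee = profile$tau[, 2],
                   tau_ankle = profile$tau[, 3], tau_paw = profile$tau[, 4])
  if (!is.null(profile$forces)) df <- cbind(df, as.data.frame(profile$forces))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_torque_profile
#' @export
read_torque_profile <- function(path) {
  df <- utils::read.csv(path)
  forces <- NULL
  if ("fx_hip" %in% names(df))
    forces <- as.matrix(df[, c(paste0("fx_", c("hip", "knee", "ankle", "paw")),
                               paste0("fy_", c("hip", "knee", "ankle", "paw")))])
  torque_profile(df$t_ms / 1000,
                 as.matrix(df[, c("tau_hip", "tau_knee", "tau_ankle",
                                  "tau_paw")]),
                 forces)
}

#' Total mechanical energy of the chain
#'
#' Kinetic (translational + rotational about each COM) plus gravitational
#' potential energy, with the hip as the potential reference.  Conserved by
#' torque-free motion; used to monitor integrator accuracy.
#'
#' @param leg a \code{leg_model}.
#' @param theta,theta_dot numeric(4) state.
#' @return energy in J.
#' @export
mechanical_energy <- function(leg, theta, theta_dot) {
  m <- leg$segments$mass; L <- leg$segments$length
  a <- leg$segments$a; I <- leg$segments$I
  e_perp <- cbind(-sin(theta), cos(theta))
  ke <- 0; pe <- 0
  v_base <- c(0, 0); y_base <- 0; x_base <- 0
  for (i in 1:4) {
    v_com <- v_base + a[i] * theta_dot[i] * e_perp[i, ]
    ke <- ke + 0.5 * m[i] * sum(v_com^2) + 0.5 * I[i] * theta_dot[i]^2
    pe <- pe + m[i] * leg$g * (y_base + a[i] * sin(theta[i]))
    v_base <- v_base + L[i] * theta_dot[i] * e_perp[i, ]
    y_base <- y_base + L[i] * sin(theta[i])
  }
  ke + pe
}

#' Simulate swing-phase motion by fixed-step RK4
#'
#' Integrates the four-link equations of motion with a fourth-order
#' Runge-Kutta scheme at fixed step \code{dt} (default 1 ms), driven by a
#' joint-torque source that is zero-order-held within each step.
#'
#' @param leg a \code{\link{leg_model}}.
#' @param theta0,theta_dot0 numeric(4): initial segment angles (rad) and
#'   angular velocities (rad/s).
#' @param torques the driving torques: a \code{\link{torque_profile}}
#'   (zero-order-held; simulation duration defaults to its length), a
#'   numeric(4) constant, or \code{function(t)} returning numeric(4).
#' @param dt integration step, s.
#' @param duration total simulated time, s.
#' @return A \code{kinematic_trajectory} object (see
#'   \code{\link{kinematic_trajectory}}): angles, angular velocities and
#'   accelerations and the toe path (world frame, using
#'   \code{leg$hip_origin}) at every step.
#' @examples
#' leg <- leg_model()
#' sim <- simulate_swing(leg, rep(-pi / 2, 4), rep(0, 4),
#'                       torques = rep(0, 4), duration = 0.1)
#' max(abs(sim$theta - rep(-pi / 2, 4)))  # hanging equilibrium: stays put
#' @export
simulate_swing <- function(leg, theta0, theta_dot0, torques,
                           dt = 0.001, duration = NULL) {
  stopifnot(inherits(leg, "leg_model"),
            length(theta0) == 4L, length(theta_dot0) == 4L)
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  if (inherits(torques, "torque_profile")) {
    if (is.null(duration)) duration <- torques$t[length(torques$t)] - torques$t[1]
    tau_fun <- function(t) zoh_torque(torques, t + torques$t[1])
  } else if (is.function(torques)) {
    tau_fun <- torques
  } else if (is.numeric(torques) && length(torques) == 4L) {
    tau_fun <- function(t) torques
  } else stop("torques must be a torque_profile, numeric(4) or function(t)")
  if (is.null(duration)) stop("duration required for non-profile torques")
  if (duration < dt) stop("duration must be at least dt")

  n <- 1L + floor(duration / dt + 1e-9)
  t <- (seq_len(n) - 1L) * dt
  theta <- matrix(NA_real_, n, 4)
  theta_dot <- matrix(NA_real_, n, 4)
  theta_ddot <- matrix(NA_real_, n, 4)
  y <- c(as.numeric(theta0), as.numeric(theta_dot0))

  deriv <- function(y, tau) {
    thdd <- angular_accelerations(leg, y[1:4], y[5:8], tau)$theta_ddot
    c(y[5:8], thdd)
  }

  for (k in seq_len(n)) {
    theta[k, ] <- y[1:4]
    theta_dot[k, ] <- y[5:8]
    tau_k <- tau_fun(t[k])
    k1 <- deriv(y, tau_k)
    theta_ddot[k, ] <- k1[5:8]
    if (k == n) break
    k2 <- deriv(y + dt / 2 * k1, tau_k)
    k3 <- deriv(y + dt / 2 * k2, tau_k)
    k4 <- deriv(y + dt * k3, tau_k)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(abs(y[5:8]) > 1e3))
      stop(sprintf("simulation diverged at step %d (t = %.3f s): |angular velocity| > 1000 rad/s",
                   k, t[k]))
  }

  L <- leg$segments$length
  toe <- cbind(leg$hip_origin[1] + cos(theta) %*% L,
               leg$hip_origin[2] + sin(theta) %*% L)
  colnames(toe) <- c("x", "y")
  kinematic_trajectory(t, theta, theta_dot, theta_ddot, toe,
                       swing_onset_index = 1L)
}
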