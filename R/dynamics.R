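#' @title The 20-equation Newton-Euler system of the four-link chain
#'
#' @description
#' Both inverse and forward dynamics solve one linear system of twenty
#' equations per time step.  Per segment there are three dynamics
#' equations,
#' \deqn{f_{x1} - f_{x2} = m \ddot x, \quad
#'       f_{y1} - f_{y2} - m g = m \ddot y,}
#' \deqn{\tau_1 - \tau_2 + a\sin\theta (f_{x1} + f_{x2})
#'       - a\cos\theta (f_{y1} + f_{y2}) = I \ddot\theta,}
#' and two kinematic-chain equations expressing the centre-of-mass linear
#' accelerations through the angles, angular velocities and angular
#' accelerations of the segment and of all segments proximal to it
#' (subscripts 1/2 denote the proximal/distal joint of a segment; the
#' distal force and torque of the toe are identically zero).  The twenty
#' unknowns are, in \emph{inverse} mode (angular accelerations known), the
#' 4 joint torques + 8 joint interaction forces + 8 linear COM
#' accelerations; in \emph{forward} mode (joint torques known) the torques
#' are replaced by the 4 angular accelerations.
#'
#' @param leg a \code{\link{leg_model}}.
#' @param theta,theta_dot numeric(4): segment angles (rad) and angular
#'   velocities (rad/s).
#' @param known numeric(4): the angular accelerations (rad/s^2, inverse
#'   mode) or joint torques (N m, forward mode).
#' @param mode \code{"inverse"} or \code{"forward"}.
#'
#' @return \code{assemble_dynamics_system}: a list of class
#'   \code{"dynamics_system"} with \code{matrix} (20 x 20), \code{rhs}
#'   (length 20), \code{unknown_layout} (labels) and \code{mode}.
#' @name dynamics_system
NULL

# Unknown layout, both modes:
#   1:4   torques tau_1..tau_4 (inverse) | angular accel thdd_1..4 (forward)
#   5:8   f_x at hip, knee, ankle, paw joints (force of segment i-1 on i)
#   9:12  f_y at the same joints
#   13:16 COM x accelerations
#   17:20 COM y accelerations

#' @rdname dynamics_system
#' @export
assemble_dynamics_system <- function(leg, theta, theta_dot, known,
                                     mode = c("inverse", "forward")) {
  mode <- match.arg(mode)
  stopifnot(inherits(leg, "leg_model"),
            length(theta) == 4L, length(theta_dot) == 4L,
            length(known) == 4L)
  if (any(!is.finite(c(theta, theta_dot, known))))
    stop("angles, velocities and known quantities must be finite")

  m <- leg$segments$mass
  L <- leg$segments$length
  a <- leg$segments$a
  I <- leg$segments$I
  g <- leg$g
  ct <- cos(theta); st <- sin(theta)

  A <- matrix(0, 20, 20)
  b <- numeric(20)

  lab <- if (mode == "inverse") paste0("tau_", 1:4) else paste0("thdd_", 1:4)
  layout <- c(lab, paste0("fx_", 1:4), paste0("fy_", 1:4),
              paste0("xdd_", 1:4), paste0("ydd_", 1:4))

  for (i in 1:4) {
    r <- 5L * (i - 1L)
    fx_i <- 4L + i; fy_i <- 8L + i
    xdd_i <- 12L + i; ydd_i <- 16L + i
    has_distal <- i < 4L

    # x force balance: fx_i - fx_{i+1} - m xdd = 0
    A[r + 1L, fx_i] <- 1
    if (has_distal) A[r + 1L, fx_i + 1L] <- -1
    A[r + 1L, xdd_i] <- -m[i]

    # y force balance: fy_i - fy_{i+1} - m ydd = m g
    A[r + 2L, fy_i] <- 1
    if (has_distal) A[r + 2L, fy_i + 1L] <- -1
    A[r + 2L, ydd_i] <- -m[i]
    b[r + 2L] <- m[i] * g

    # moment about the COM:
    # tau_i - tau_{i+1} + a sin(th) (fx_i + fx_{i+1})
    #                   - a cos(th) (fy_i + fy_{i+1}) = I thdd_i
    A[r + 3L, fx_i] <- a[i] * st[i]
    A[r + 3L, fy_i] <- -a[i] * ct[i]
    if (has_distal) {
      A[r + 3L, fx_i + 1L] <- a[i] * st[i]
      A[r + 3L, fy_i + 1L] <- -a[i] * ct[i]
    }
    if (mode == "inverse") {
      A[r + 3L, i] <- 1
      if (has_distal) A[r + 3L, i + 1L] <- -1
      b[r + 3L] <- I[i] * known[i]
    } else {
      A[r + 3L, i] <- -I[i]
      b[r + 3L] <- -known[i] + if (has_distal) known[i + 1L] else 0
    }

    # chain kinematics: COM acceleration of segment i through the angles
    # of segments 1..i (full length L for proximal links, half length a
    # for the segment's own COM term)
    A[r + 4L, xdd_i] <- 1
    A[r + 5L, ydd_i] <- 1
    for (j in 1:i) {
      r_j <- if (j < i) L[j] else a[i]
      cent_x <- -r_j * ct[j] * theta_dot[j]^2
      cent_y <- -r_j * st[j] * theta_dot[j]^2
      b[r + 4L] <- b[r + 4L] + cent_x
      b[r + 5L] <- b[r + 5L] + cent_y
      if (mode == "inverse") {
        b[r + 4L] <- b[r + 4L] - r_j * st[j] * known[j]
        b[r + 5L] <- b[r + 5L] + r_j * ct[j] * known[j]
      } else {
        A[r + 4L, j] <- A[r + 4L, j] + r_j * st[j]
        A[r + 5L, j] <- A[r + 5L, j] - r_j * ct[j]
      }
    }
  }

  structure(list(matrix = A, rhs = b, unknown_layout = layout, mode = mode),
            class = "dynamics_system")
}

solve_dynamics_system <- function(sys) {
  x <- tryCatch(solve(sys$matrix, sys$rhs),
                error = function(e)
                  stop("singular dynamics system: ", conditionMessage(e),
                       call. = FALSE))
  names(x) <- sys$unknown_layout
  x
}

#' Inverse dynamics at a single state
#'
#' Solves the inverse-mode system: given the leg state and the segment
#' angular accelerations, returns the four joint torques and the joint
#' interaction forces.
#'
#' @inheritParams dynamics_system
#' @param theta_ddot numeric(4), segment angular accelerations (rad/s^2).
#' @return list with \code{tau} (4 torques: hip, knee, ankle, paw; N m,
#'   anticlockwise-positive), \code{fx}, \code{fy} (4 joint interaction
#'   forces each, N), \code{xdd}, \code{ydd} (COM accelerations, m/s^2).
#' @examples
#' leg <- leg_model()
#' # static horizontal leg: hip torque = g * sum(m_i x_com,i) = 0.3953 N m
#' inverse_dynamics_state(leg, rep(0, 4), rep(0, 4), rep(0, 4))$tau
#' @export
inverse_dynamics_state <- function(leg, theta, theta_dot, theta_ddot) {
  sys <- assemble_dynamics_system(leg, theta, theta_dot, theta_ddot,
                                  mode = "inverse")
  x <- solve_dynamics_system(sys)
  joints <- c("hip", "knee", "ankle", "paw")
  list(tau = stats::setNames(x[1:4], joints),
       fx = stats::setNames(x[5:8], joints),
       fy = stats::setNames(x[9:12], joints),
       xdd = x[13:16], ydd = x[17:20])
}

#' Forward dynamics at a single state
#'
#' Solves the forward-mode system: given the leg state and the four joint
#' torques, returns the segment angular accelerations (plus interaction
#' forces and COM accelerations).
#'
#' @inheritParams dynamics_system
#' @param tau numeric(4), joint torques (hip, knee, ankle, paw), N m.
#' @return list with \code{theta_ddot} (rad/s^2), \code{fx}, \code{fy},
#'   \code{xdd}, \code{ydd}.
#' @export
angular_accelerations <- function(leg, theta, theta_dot, tau) {
  sys <- assemble_dynamics_system(leg, theta, theta_dot, tau,
                                  mode = "forward")
  x <- solve_dynamics_system(sys)
  joints <- c("hip", "knee", "ankle", "paw")
  list(theta_ddot = unname(x[1:4]),
       fx = stats::setNames(x[5:8], joints),
       fy = stats::setNames(x[9:12], joints),
       xdd = x[13:16], ydd = x[17:20])
}
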