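#' Four-link planar leg model
#'
#' Constructs the rigid-rod model of a cat hind leg used throughout the
#' package: four uniform rods (thigh, shank, paw, toes) chained at the hip,
#' knee, ankle and paw joints.  Each segment is described by its mass, its
#' length, its half-length \code{a = length/2} and its moment of inertia
#' about the centre of mass, \code{I = m a^2 / 3} (uniform rod).  Segment
#' angles are measured anticlockwise from the positive x axis at the
#' segment's proximal joint; positive torques are anticlockwise; gravity
#' acts in \code{-y}.
#'
#' The default parameters are those estimated for adult cats: masses
#' 200/100/40/20 g and lengths 10/11/5/2 cm (thigh/shank/paw/toes), with a
#' 6.5 cm barrier.  All quantities are stored in SI units (m, kg, s, N m);
#' centimetres appear only in trial files on disk.
#'
#' @param masses numeric(4), segment masses in kg (thigh, shank, paw, toe).
#' @param lengths numeric(4), segment lengths in m.
#' @param g gravitational acceleration, m/s^2 (stored positive).
#' @param hip_origin numeric(2), world position of the hip joint in m.
#'   The hip is treated as a fixed inertial origin: the chain's equations of
#'   motion contain no base-translation terms.
#' @param barrier_x world x position of the (remembered) barrier, m.
#' @param barrier_height barrier height, m.
#'
#' @return An object of class \code{"leg_model"}: a list with elements
#'   \code{segments} (data frame with \code{name}, \code{mass},
#'   \code{length}, \code{a}, \code{I}), \code{g}, \code{hip_origin},
#'   \code{barrier_x}, \code{barrier_height}.
#' @examples
#' leg <- leg_model()
#' leg$segments
#' @export
leg_model <- function(masses = c(0.200, 0.100, 0.040, 0.020),
                      lengths = c(0.10, 0.11, 0.05, 0.02),
                      g = 9.81,
                      hip_origin = c(0, 0),
                      barrier_x = 0.60,
                      barrier_height = 0.065) {
  masses <- as.numeric(masses)
  lengths <- as.numeric(lengths)
  if (length(masses) != 4L || length(lengths) != 4L)
    stop("a four-link leg needs exactly 4 masses and 4 lengths")
  if (any(!is.finite(masses)) || any(masses <= 0))
    stop("segment masses must be finite and > 0")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("segment lengths must be finite and > 0")
  if (!is.finite(g) || g <= 0)
    stop("g must be finite and > 0 (gravity acts in -y)")
  a <- lengths / 2
  segments <- data.frame(
    name = c("thigh", "shank", "paw", "toe"),
    mass = masses,
    length = lengths,
    a = a,
    I = masses * a^2 / 3,
    stringsAsFactors = FALSE
  )
  structure(
    list(segments = segments, g = g,
         hip_origin = as.numeric(hip_origin),
         barrier_x = as.numeric(barrier_x),
         barrier_height = as.numeric(barrier_height)),
    class = "leg_model"
  )
}

#' @export
print.leg_model <- function(x, ...) {
  cat("Four-link planar leg model (uniform rigid rods)\n")
  seg <- x$segments
  cat(sprintf("  %-6s m = %.3f kg  L = %.3f m  I = %.3e kg m^2\n",
              seg$name, seg$mass, seg$length, seg$I), sep = "")
  cat(sprintf("  g = %.2f m/s^2, hip origin = (%.3f, %.3f) m\n",
              x$g, x$hip_origin[1], x$hip_origin[2]))
  cat(sprintf("  barrier: x = %.3f m, height = %.3f m\n",
              x$barrier_x, x$barrier_height))
  invisible(x)
}

#' Default cat hind-leg geometry
#'
#' Convenience wrapper returning \code{\link{leg_model}()} with its default
#' cat parameters (masses 0.2/0.1/0.04/0.02 kg, lengths
#' 0.10/0.11/0.05/0.02 m, 6.5 cm barrier, g = 9.81).
#'
#' @return A \code{leg_model} object.
#' @export
make_default_cat_leg <- function() leg_model()

#' Read a leg geometry from a key-value config file
#'
#' Reads a YAML (or JSON) file with any of the keys \code{masses},
#' \code{lengths} (length-4 vectors), \code{g}, \code{hip_origin},
#' \code{barrier_x}, \code{barrier_height}; missing keys fall back to the
#' cat defaults.  Units in the file are SI.
#'
#' @param path file path.
#' @return A \code{leg_model} object.
#' @export
read_leg_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- formals(leg_model)
  args <- list()
  for (key in c("masses", "lengths", "g", "hip_origin",
                "barrier_x", "barrier_height")) {
    if (!is.null(cfg[[key]])) args[[key]] <- cfg[[key]]
  }
  do.call(leg_model, args)
}

#' Joint and centre-of-mass positions of the chain
#'
#' Forward kinematics: positions (m, relative to the hip origin) of the
#' five chain points (hip, knee, ankle, paw joint, toe tip) and of the four
#' segment centres of mass, for given segment angles.
#'
#' @param leg a \code{leg_model}.
#' @param theta numeric(4), segment angles in rad (anticlockwise from +x).
#' @return list with \code{joints} (5 x 2 matrix, rows hip/knee/ankle/
#'   paw_joint/toe) and \code{coms} (4 x 2 matrix, rows thigh/shank/paw/toe).
#' @examples
#' pos <- joint_and_com_positions(leg_model(), rep(-pi / 2, 4))
#' pos$joints["toe", ]  # hanging straight down: (0, -0.28)
#' @export
joint_and_com_positions <- function(leg, theta) {
  stopifnot(inherits(leg, "leg_model"), length(theta) == 4L)
  L <- leg$segments$length
  a <- leg$segments$a
  u <- cbind(cos(theta), sin(theta))
  joints <- matrix(0, 5, 2,
                   dimnames = list(c("hip", "knee", "ankle", "paw_joint",
                                     "toe"), c("x", "y")))
  for (i in 1:4) joints[i + 1, ] <- joints[i, ] + L[i] * u[i, ]
  coms <- joints[1:4, , drop = FALSE] + a * u
  rownames(coms) <- leg$segments$name
  list(joints = joints, coms = coms)
}

#' Closed-form static gravitational joint torques
#'
#' For a motionless posture the net torque a joint must carry equals the
#' gravitational moment of all segments distal to it about that joint:
#' \code{tau_j = g * sum_i m_i (x_com,i - x_joint,j)} over distal segments
#' \code{i} (anticlockwise-positive).  Used as the independent oracle for
#' the inverse-dynamics solver.
#'
#' @param leg a \code{leg_model}.
#' @param theta numeric(4) segment angles, rad.
#' @return numeric(4): static torques at hip, knee, ankle, paw joint (N m).
#' @export
static_joint_torques <- function(leg, theta) {
  pos <- joint_and_com_positions(leg, theta)
  m <- leg$segments$mass
  tau <- numeric(4)
  for (j in 1:4) {
    idx <- j:4
    tau[j] <- leg$g * sum(m[idx] * (pos$coms[idx, 1] - pos$joints[j, 1]))
  }
  names(tau) <- c("hip", "knee", "ankle", "paw")
  tau
}
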