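#' Kinematic trajectory container
#'
#' Segment angles, angular velocities and accelerations on a uniform time
#' grid (1 ms for pipeline output), plus the toe-tip path in the world
#' frame and the detected swing-onset sample.
#'
#' @param t time vector, s, uniform spacing.
#' @param theta,theta_dot,theta_ddot n x 4 matrices (rad, rad/s, rad/s^2),
#'   columns thigh, shank, paw, toe.
#' @param toe_path n x 2 matrix of toe-tip world positions, m (forward
#'   kinematics of the segment angles about the fixed hip).
#' @param swing_onset_index sample index of swing onset.
#' @param ground_y world y of the ground (standing toe height), m.
#' @param hip_origin world position of the (fixed) hip, m.
#' @param toe_path_marker optional n x 2 matrix: the toe path obtained
#'   directly from the digitized toe marker (filtered and resampled);
#'   used for the trajectory metrics (onset, slope, distance) when
#'   present, mirroring the separate digitization of the toe tip.
#' @return object of class \code{"kinematic_trajectory"}.
#' @export
kinematic_trajectory <- function(t, theta, theta_dot, theta_ddot, toe_path,
                                 swing_onset_index = 1L, ground_y = 0,
                                 hip_origin = c(0, 0),
                                 toe_path_marker = NULL) {
  n <- length(t)
  theta <- as.matrix(theta); theta_dot <- as.matrix(theta_dot)
  theta_ddot <- as.matrix(theta_ddot); toe_path <- as.matrix(toe_path)
  if (nrow(theta) != n || nrow(theta_dot) != n || nrow(theta_ddot) != n ||
      nrow(toe_path) != n)
    stop("all series must have the same length as t")
  if (n > 1) {
    dt <- diff(t)
    if (max(abs(dt - dt[1])) > 1e-9) stop("t must be uniformly spaced")
  }
  colnames(theta) <- colnames(theta_dot) <- colnames(theta_ddot) <-
    c("thigh", "shank", "paw", "toe")
  colnames(toe_path) <- c("x", "y")
  if (!is.null(toe_path_marker)) {
    toe_path_marker <- as.matrix(toe_path_marker)
    if (nrow(toe_path_marker) != n)
      stop("toe_path_marker must share the trajectory time base")
    colnames(toe_path_marker) <- c("x", "y")
  }
  structure(list(t = as.numeric(t), theta = theta, theta_dot = theta_dot,
                 theta_ddot = theta_ddot, toe_path = toe_path,
                 swing_onset_index = as.integer(swing_onset_index),
                 ground_y = ground_y, hip_origin = as.numeric(hip_origin),
                 toe_path_marker = toe_path_marker),
            class = "kinematic_trajectory")
}

#' @export
print.kinematic_trajectory <- function(x, ...) {
  dt <- if (length(x$t) > 1) x$t[2] - x$t[1] else NA
  cat(sprintf("Kinematic trajectory: %d samples, dt = %.3g ms, onset at sample %d (t = %.3f s)\n",
              length(x$t), 1000 * dt, x$swing_onset_index,
              x$t[x$swing_onset_index]))
  invisible(x)
}

#' Knee position by triangulation
#'
#' The knee marker cannot be tracked reliably (large skin movement), so the
#' knee centre is reconstructed as the circle-circle intersection at
#' \code{thigh_len} from the hip and \code{shank_len} from the ankle,
#' taking the anatomical (anterior, larger-x) solution.
#'
#' @param hip,ankle 2-vectors or n x 2 matrices of positions, m.
#' @param thigh_len,shank_len segment lengths, m.
#' @param tol reachability tolerance, m: a hip-ankle distance outside the
#'   annulus \code{[|thigh-shank|, thigh+shank]} by more than \code{tol} is
#'   an error; within it, the configuration is clamped to the collinear
#'   boundary.  The pipeline passes a larger tolerance than the 1e-6
#'   default to absorb marker noise near full extension.
#' @return knee position(s), same shape as the input.
#' @examples
#' triangulate_knee(c(0, 0), c(0, -0.15), 0.10, 0.11)
#' @export
triangulate_knee <- function(hip, ankle, thigh_len, shank_len, tol = 1e-6) {
  vec_in <- is.null(dim(hip))
  hip <- rbind(hip); ankle <- rbind(ankle)
  d <- sqrt(rowSums((ankle - hip)^2))
  lo <- abs(thigh_len - shank_len); hi <- thigh_len + shank_len
  if (any(d > hi + tol | d < lo - tol))
    stop(sprintf("hip-ankle distance outside reachable annulus [%.4f, %.4f] m (worst %.4f m)",
                 lo, hi, max(pmax(d - hi, lo - d))))
  d <- pmin(pmax(d, lo), hi)
  u <- (ankle - hip) / d
  tt <- (d^2 + thigh_len^2 - shank_len^2) / (2 * d)
  h <- sqrt(pmax(thigh_len^2 - tt^2, 0))
  # two candidates on either side of the hip-ankle line; take the anterior
  # (larger x; larger y used as the tie-break for a horizontal line)
  perp <- cbind(-u[, 2], u[, 1])
  k1 <- hip + tt * u + h * perp
  k2 <- hip + tt * u - h * perp
  pick1 <- k1[, 1] > k2[, 1] |
    (abs(k1[, 1] - k2[, 1]) < 1e-12 & k1[, 2] >= k2[, 2])
  knee <- ifelse(cbind(pick1, pick1), k1, k2)
  dim(knee) <- dim(k1)
  if (vec_in) knee <- drop(knee)
  knee
}

# continuous unwrap of a wrapped angle series
unwrap_angle <- function(x) {
  d <- diff(x)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(x[1], x[1] + cumsum(d))
}

#' Segment angles from trial markers
#'
#' Computes the four segment angle series (rad, anticlockwise from +x,
#' unwrapped to be continuous in time) at the capture rate: thigh from
#' hip to the triangulated knee, shank from knee to ankle, paw from ankle
#' to paw joint, toe from paw joint to toe tip.
#'
#' @param trial a \code{\link{leg_trial}}.
#' @param leg a \code{\link{leg_model}} (thigh/shank lengths for the knee
#'   triangulation).
#' @param knee_tol reachability tolerance passed to
#'   \code{\link{triangulate_knee}}.
#' @return n x 4 matrix of angles at the trial's capture rate.
#' @export
segment_angles <- function(trial, leg, knee_tol = 2e-3) {
  stopifnot(inherits(trial, "leg_trial"), inherits(leg, "leg_model"))
  mk <- trial$markers
  knee <- triangulate_knee(mk$hip, mk$ankle, leg$segments$length[1],
                           leg$segments$length[2], tol = knee_tol)
  seg_ends <- list(list(mk$hip, knee), list(knee, mk$ankle),
                   list(mk$ankle, mk$paw_joint), list(mk$paw_joint, mk$toe))
  th <- sapply(seg_ends, function(se) {
    dxy <- se[[2]] - se[[1]]
    if (any(rowSums(dxy^2) < 1e-16))
      stop("degenerate (zero-length) segment vector in markers")
    unwrap_angle(atan2(dxy[, 2], dxy[, 1]))
  })
  colnames(th) <- c("thigh", "shank", "paw", "toe")
  th
}

#' Zero-phase Butterworth low-pass filter
#'
#' Second-order Butterworth applied forward and backward (zero phase, so
#' the effective attenuation at the cutoff is -6 dB), with odd-reflection
#' end padding so that constants pass exactly and end transients do not
#' leak into the series.
#'
#' @param x numeric series.
#' @param fs sampling rate, Hz.
#' @param cutoff cutoff frequency, Hz (must be below \code{fs/2}).
#' @param order filter order (default 2).
#' @return filtered series, same length.
#' @export
zero_phase_butter <- function(x, fs, cutoff, order = 2) {
  if (cutoff >= fs / 2)
    stop(sprintf("cutoff (%g Hz) must be below the Nyquist rate (%g Hz)",
                 cutoff, fs / 2))
  n <- length(x)
  padlen <- min(n - 1L, max(9L, ceiling(8 * fs / cutoff)))
  if (padlen < 1L) stop("series too short to filter")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  pre <- 2 * x[1] - x[padlen + 1 - seq_len(padlen) + 1]
  post <- 2 * x[n] - x[n - seq_len(padlen)]
  xp <- c(pre, x, post)
  y <- as.numeric(signal::filter(bf, xp))
  y <- rev(as.numeric(signal::filter(bf, rev(y))))
  y[(padlen + 1):(padlen + n)]
}

#' Filter and resample a series to 1-ms resolution
#'
#' Applies the zero-phase 10-Hz Butterworth filter at the capture rate and
#' interpolates the result to a 1-ms grid with a cubic spline.
#'
#' @param x series sampled at \code{fs}.
#' @param fs capture rate, Hz.
#' @param cutoff low-pass cutoff, Hz.
#' @param dt_out output sample interval, s.
#' @return list with \code{t} (s, starting at 0) and \code{y}.
#' @export
filter_and_resample <- function(x, fs, cutoff = 10, dt_out = 0.001) {
  n <- length(x)
  if (n / fs < 0.5)
    stop("need at least 0.5 s of data (filter transients)")
  xf <- zero_phase_butter(x, fs, cutoff)
  t_in <- (seq_len(n) - 1) / fs
  t_out <- seq(0, t_in[n], by = dt_out)
  y <- stats::spline(t_in, xf, xout = t_out, method = "fmm")$y
  list(t = t_out, y = y)
}

#' Forward first-difference derivative
#'
#' \code{(x[k+1] - x[k]) / dt}, with the last value repeated to preserve
#' length; applied twice to obtain accelerations.
#'
#' @param x series.
#' @param dt sample interval, s.
#' @return derivative series of the same length.
#' @export
differentiate <- function(x, dt) {
  if (length(x) < 2) stop("need at least 2 samples to differentiate")
  d <- diff(x) / dt
  c(d, d[length(d)])
}

#' Re-centred finite-difference derivative
#'
#' The 1-ms time difference \code{(x[k+1] - x[k]) / dt} estimates the
#' derivative at the midpoint \code{t_k + dt/2}, not at \code{t_k}.
#' Averaging the two adjacent forward differences re-centres the estimate
#' on the sample (one-sided differences at the ends).  The processing
#' pipeline uses this form: the half-sample lead of raw forward
#' differences otherwise propagates into a systematic torque-timing error
#' that biases the inverse-to-forward round trip by about a millimetre of
#' toe position over 200 ms.
#'
#' @inheritParams differentiate
#' @return derivative series of the same length.
#' @export
differentiate_centered <- function(x, dt) {
  n <- length(x)
  if (n < 2) stop("need at least 2 samples to differentiate")
  if (n == 2) return(rep((x[2] - x[1]) / dt, 2))
  c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1]) / dt
}

#' Detect swing onset from the toe path
#'
#' Swing onset is the first sample at which the toe height exceeds its
#' standing baseline (median over the first 100 ms) by \code{rise} and
#' stays above that level for at least \code{persist}.
#'
#' @param toe_path n x 2 matrix of toe positions (m) or a numeric vector of
#'   toe heights.
#' @param dt sample interval, s.
#' @param rise required elevation above baseline, m (default 5 mm).
#' @param persist required persistence, s (default 50 ms).
#' @param baseline_window duration used for the baseline median, s.
#' @return sample index of onset.
#' @export
detect_swing_onset <- function(toe_path, dt, rise = 0.005, persist = 0.05,
                               baseline_window = 0.1) {
  y <- if (is.matrix(toe_path)) toe_path[, 2] else as.numeric(toe_path)
  n <- length(y)
  nb <- max(1L, min(n, round(baseline_window / dt)))
  thr <- stats::median(y[seq_len(nb)]) + rise
  np <- max(1L, round(persist / dt))
  above <- y >= thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ok <- which(runs$values & runs$lengths >= np + 1L)
  if (!length(ok))
    stop(sprintf("no swing onset: toe never stays %.1f cm above baseline for %.0f ms",
                 100 * rise, 1000 * persist))
  starts[ok[1]]
}

#' Toe-trajectory slope between 3 and 5 cm elevation
#'
#' Dimensionless upslope of the early swing trajectory: the 2-cm change in
#' height divided by the horizontal progress as the toe first rises
#' through 3 cm and then through 5 cm above the ground, crossings located
#' by linear interpolation between samples.
#'
#' @param toe_path n x 2 matrix of toe positions, m.
#' @param onset_index sample from which to search for the crossings.
#' @param ground_y world height of the ground (standing toe height), m.
#' @param h1,h2 the two elevations, m (defaults 3 and 5 cm).
#' @return the slope.  If the toe moves backward between the two heights
#'   the (negative or infinite) value is returned with a warning and
#'   attribute \code{flagged = TRUE}.
#' @export
toe_trajectory_slope <- function(toe_path, onset_index = 1L, ground_y = 0,
                                 h1 = 0.03, h2 = 0.05) {
  x <- toe_path[, 1]
  y <- toe_path[, 2] - ground_y
  cross_x <- function(level) {
    # first j > onset with y[j-1] < level <= y[j]
    idx <- seq(onset_index + 1L, length(y))
    j <- idx[y[idx] >= level & y[idx - 1L] < level]
    if (!length(j)) return(NA_real_)
    j <- j[1]
    frac <- (level - y[j - 1L]) / (y[j] - y[j - 1L])
    x[j - 1L] + frac * (x[j] - x[j - 1L])
  }
  x1 <- cross_x(h1)
  x2 <- cross_x(h2)
  if (is.na(x1) || is.na(x2))
    stop(sprintf("toe never rises through %.0f and %.0f cm after onset",
                 100 * h1, 100 * h2))
  dx <- x2 - x1
  slope <- (h2 - h1) / dx
  if (dx <= 0) {
    warning("toe moved backward between the two heights; slope flagged")
    attr(slope, "flagged") <- TRUE
  }
  slope
}

#' Initial toe-to-barrier distance
#'
#' Horizontal distance from the toe at swing onset to the (remembered)
#' barrier: \code{barrier_x - toe_x(onset)}; positive when the toe starts
#' behind the barrier.
#'
#' @param barrier_x world x of the barrier, m.
#' @param toe_path n x 2 toe path, m (world frame).
#' @param onset_index swing-onset sample.
#' @return distance, m.
#' @export
initial_toe_to_barrier_distance <- function(barrier_x, toe_path,
                                            onset_index = 1L) {
  unname(barrier_x - toe_path[onset_index, 1])
}

#' Process a raw trial into a 1-ms kinematic trajectory
#'
#' The motion-capture pipeline: triangulate the knee, form the four
#' segment-angle series, low-pass filter them (zero-phase 2nd-order
#' Butterworth, 10 Hz) at the capture rate, cubic-spline them to a 1-ms
#' grid, differentiate twice by re-centred 1-ms differences
#' (\code{\link{differentiate_centered}}), rebuild the toe
#' path by forward kinematics about the fixed hip (mean hip-marker
#' position), and detect swing onset.
#'
#' @param trial a \code{\link{leg_trial}}.
#' @param leg a \code{\link{leg_model}}.
#' @param cutoff angle filter cutoff, Hz.
#' @param knee_tol knee-triangulation reachability tolerance, m.
#' @return a \code{\link{kinematic_trajectory}} (world-frame toe path;
#'   \code{ground_y} is the standing toe baseline).
#' @export
process_trial <- function(trial, leg, cutoff = 10, knee_tol = 2e-3) {
  stopifnot(inherits(trial, "leg_trial"))
  th_raw <- segment_angles(trial, leg, knee_tol = knee_tol)
  fs <- trial$sample_rate
  res <- apply(th_raw, 2, filter_and_resample, fs = fs, cutoff = cutoff,
               simplify = FALSE)
  t_out <- res[[1]]$t
  theta <- sapply(res, `[[`, "y")
  dt <- t_out[2] - t_out[1]
  theta_dot <- apply(theta, 2, differentiate_centered, dt = dt)
  theta_ddot <- apply(theta_dot, 2, differentiate_centered, dt = dt)
  hip <- colMeans(trial$markers$hip)
  L <- leg$segments$length
  toe <- cbind(hip[1] + cos(theta) %*% L, hip[2] + sin(theta) %*% L)
  # the toe tip is digitized in its own right: resample the marker series
  # directly (unfiltered spline) for the trajectory metrics
  t_in <- (seq_len(nrow(trial$markers$toe)) - 1) / fs
  toe_mk <- sapply(1:2, function(j)
    stats::spline(t_in, trial$markers$toe[, j], xout = t_out,
                  method = "fmm")$y)
  onset <- detect_swing_onset(toe_mk, dt)
  nb <- max(1L, min(nrow(toe_mk), round(0.1 / dt)))
  ground <- stats::median(toe_mk[seq_len(nb), 2])
  kinematic_trajectory(t_out, theta, theta_dot, theta_ddot, toe,
                       swing_onset_index = onset, ground_y = ground,
                       hip_origin = hip, toe_path_marker = toe_mk)
}
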