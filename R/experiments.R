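#' Select trials by initial distance
#'
#' Subset of a trial-metrics table with
#' \code{min_distance <= distance <= max_distance} (both ends inclusive).
#' The long-distance subset used for torque averaging is 16-25 cm; the
#' short-distance subset is below 8 cm.
#'
#' @param metrics data frame with a \code{distance} column (m).
#' @param min_distance,max_distance bounds, m.
#' @return the subset (possibly empty, with a warning).
#' @export
select_subset <- function(metrics, min_distance = 0.16,
                          max_distance = 0.25) {
  out <- metrics[!is.na(metrics$distance) &
                   metrics$distance >= min_distance &
                   metrics$distance <= max_distance, , drop = FALSE]
  if (!nrow(out))
    warning(sprintf("no trials with distance in [%.2f, %.2f] m",
                    min_distance, max_distance))
  out
}

#' Ordinary least-squares regression with a slope t-test
#'
#' Simple linear regression of \code{y} on \code{x} (via \code{stats::lm})
#' reporting the slope, intercept, R^2, the two-sided p-value of the slope
#' t-test on n - 2 degrees of freedom, and n.  Pairs with missing values
#' are dropped.
#'
#' @param x,y numeric vectors.
#' @return object of class \code{"fourlink_regression"}: list with
#'   \code{slope}, \code{intercept}, \code{r_squared}, \code{p_value},
#'   \code{n}, \code{slope_ci} (95\%) and the underlying \code{lm} fit.
#' @export
linear_regression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete (x, y) pairs")
  if (max(x) - min(x) < 1e-12)
    stop("degenerate regression: x is constant")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  ss_tot <- sum((y - mean(y))^2)
  degenerate_y <- ss_tot < 1e-12 * length(y) * max(1, mean(y)^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (degenerate_y) 0 else sm$r.squared,
                 p_value = if (degenerate_y) 1 else sm$coefficients[2, 4],
                 n = length(x),
                 slope_ci = unname(suppressWarnings(stats::confint(fit))[2, ]),
                 fit = fit),
            class = "fourlink_regression")
}

#' @export
print.fourlink_regression <- function(x, ...) {
  cat(sprintf("OLS: slope %+.4g (95%% CI %+.4g..%+.4g), intercept %+.4g, R^2 = %.3f, p = %.3g, n = %d\n",
              x$slope, x$slope_ci[1], x$slope_ci[2], x$intercept,
              x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Fixed-command forward experiment
#'
#' Drives the forward model with one torque profile (typically the average
#' of the long-distance subset) and the same initial angular velocities
#' from each trial's own initial geometry, and measures the simulated
#' toe-trajectory slope against the initial toe-to-barrier distance.
#' This isolates the purely mechanical contribution of leg geometry: any
#' rise of slope with proximity here requires no change in the command.
#'
#' @param leg a \code{\link{leg_model}}.
#' @param avg_profile the driving \code{\link{torque_profile}} (at least
#'   200 ms).
#' @param avg_initial_velocities numeric(4), rad/s.
#' @param initial_geometries list of records with \code{theta} (rad) and
#'   optionally \code{hip} (world hip position, default
#'   \code{leg$hip_origin}) and \code{ground_y} (default 0).
#' @param barrier_x world barrier position, m.
#' @return data frame with \code{distance} (m) and \code{simulated_slope}
#'   (NA, with a warning, for simulations whose toe never reaches 5 cm).
#' @export
run_fixed_command_experiment <- function(leg, avg_profile,
                                         avg_initial_velocities,
                                         initial_geometries,
                                         barrier_x = leg$barrier_x) {
  dur <- avg_profile$t[length(avg_profile$t)] - avg_profile$t[1]
  if (dur < 0.2 - 1e-9)
    stop("the driving profile must cover at least 200 ms")
  res <- lapply(initial_geometries, function(geo) {
    leg_w <- leg
    leg_w$hip_origin <- if (!is.null(geo$hip)) geo$hip else leg$hip_origin
    ground <- if (!is.null(geo$ground_y)) geo$ground_y else 0
    sim <- simulate_swing(leg_w, geo$theta, avg_initial_velocities,
                          torques = avg_profile)
    slope <- tryCatch(
      as.numeric(toe_trajectory_slope(sim$toe_path, 1L, ground_y = ground)),
      error = function(e) NA_real_)
    c(distance = barrier_x - sim$toe_path[1, 1], simulated_slope = slope)
  })
  out <- as.data.frame(do.call(rbind, res))
  if (anyNA(out$simulated_slope))
    warning(sprintf("%d simulation(s) never reached 5 cm toe elevation",
                    sum(is.na(out$simulated_slope))))
  out
}

#' Full barrier-stepping analysis of a trial cohort
#'
#' Orchestrates the complete analysis, per animal: per-trial kinematics
#' and inverse dynamics (\code{\link{fit_swing_dynamics}}), averaging of
#' the long-distance-subset torque profiles and initial angular
#' velocities, fixed-command forward simulations from every trial's
#' initial geometry, and the regressions: actual slope vs distance,
#' simulated slope vs distance, simulated vs actual slope (the
#' mechanical-vs-neuronal comparison: a slope below 1 means the fixed
#' command under-predicts the steepening seen in the data), initial
#' hip/knee/ankle torque vs distance, and EMG burst magnitude vs
#' distance.  Trials failing any stage are excluded and logged.
#'
#' @param trials list of \code{\link{leg_trial}} objects.
#' @param leg a \code{\link{leg_model}}.
#' @param subset_range distance range (m) of the torque-averaging subset.
#' @param avg_duration length of the averaged command, s.
#' @param ... passed to \code{\link{fit_swing_dynamics}}.
#' @return object of class \code{"barrier_analysis"}: \code{metrics}
#'   (data frame: trial_id, animal, distance, actual_slope,
#'   simulated_slope, hip/knee/ankle/paw_tau0, emg_* columns),
#'   \code{regressions} (per animal, list of
#'   \code{\link{linear_regression}} results or \code{NULL} where not
#'   estimable), \code{avg_profile} (per animal), \code{fits},
#'   \code{excluded} (data frame of trial_id + reason).
#' @export
run_full_analysis <- function(trials, leg = leg_model(),
                              subset_range = c(0.16, 0.25),
                              avg_duration = 0.200, ...) {
  fits <- list(); excluded <- list()
  for (tr in trials) {
    f <- tryCatch(fit_swing_dynamics(tr, leg, ...), error = function(e) e)
    if (inherits(f, "error"))
      excluded[[length(excluded) + 1L]] <-
        data.frame(trial_id = tr$trial_id, reason = conditionMessage(f))
    else fits[[tr$trial_id]] <- f
  }
  excluded <- if (length(excluded)) do.call(rbind, excluded)
              else data.frame(trial_id = character(), reason = character())
  if (length(excluded$trial_id))
    message(sprintf("%d trial(s) excluded: %s", nrow(excluded),
                    paste(excluded$trial_id, collapse = ", ")))
  if (!length(fits)) stop("no trial could be analysed")

  metrics <- do.call(rbind, lapply(fits, function(f) {
    m <- f$metrics
    row <- data.frame(trial_id = f$trial$trial_id,
                      animal = if (!is.null(f$trial$meta$animal))
                        f$trial$meta$animal else "A",
                      distance = m$distance,
                      actual_slope = m$slope,
                      hip_tau0 = m$tau0[1], knee_tau0 = m$tau0[2],
                      ankle_tau0 = m$tau0[3], paw_tau0 = m$tau0[4],
                      stringsAsFactors = FALSE)
    for (ch in names(m$emg_magnitude))
      row[[paste0("emg_", ch)]] <- m$emg_magnitude[[ch]]
    row
  }))
  rownames(metrics) <- NULL
  metrics$simulated_slope <- NA_real_

  regressions <- list(); avg_profiles <- list()
  for (an in unique(metrics$animal)) {
    sel <- metrics$animal == an
    man <- metrics[sel, ]
    sub <- select_subset(man, subset_range[1], subset_range[2])
    if (!nrow(sub)) {
      regressions[[an]] <- list()
      next
    }
    sub_fits <- fits[sub$trial_id]
    avg_prof <- average_torque_profiles(lapply(sub_fits, `[[`, "torques"),
                                        duration = avg_duration)
    avg_vel <- colMeans(do.call(rbind, lapply(sub_fits, function(f)
      f$trajectory$theta_dot[f$trajectory$swing_onset_index, ])))
    geoms <- lapply(fits[man$trial_id], function(f) {
      i0 <- f$trajectory$swing_onset_index
      list(theta = f$trajectory$theta[i0, ], hip = f$trajectory$hip_origin,
           ground_y = f$trajectory$ground_y)
    })
    fc <- run_fixed_command_experiment(leg, avg_prof, avg_vel, geoms,
                                       barrier_x = leg$barrier_x)
    metrics$simulated_slope[sel] <- fc$simulated_slope
    man$simulated_slope <- fc$simulated_slope

    reg <- function(x, y) tryCatch(linear_regression(x, y),
                                   error = function(e) NULL)
    rl <- list(actual_slope_vs_distance = reg(man$distance, man$actual_slope),
               simulated_slope_vs_distance =
                 reg(man$distance, man$simulated_slope),
               simulated_vs_actual_slope =
                 reg(man$actual_slope, man$simulated_slope),
               hip_tau0_vs_distance = reg(man$distance, man$hip_tau0),
               knee_tau0_vs_distance = reg(man$distance, man$knee_tau0),
               ankle_tau0_vs_distance = reg(man$distance, man$ankle_tau0))
    for (ch in grep("^emg_", names(man), value = TRUE))
      rl[[paste0(ch, "_vs_distance")]] <- reg(man$distance, man[[ch]])
    regressions[[an]] <- rl
    avg_profiles[[an]] <- avg_prof
  }

  structure(list(metrics = metrics, regressions = regressions,
                 avg_profile = avg_profiles, fits = fits,
                 excluded = excluded, leg = leg,
                 subset_range = subset_range),
            class = "barrier_analysis")
}

#' @export
print.barrier_analysis <- function(x, ...) {
  cat(sprintf("Barrier-stepping analysis: %d trial(s) analysed, %d excluded, %d animal(s)\n",
              nrow(x$metrics), nrow(x$excluded),
              length(unique(x$metrics$animal))))
  for (an in names(x$regressions)) {
    rl <- x$regressions[[an]]
    if (!length(rl)) next
    cat(sprintf("animal %s:\n", an))
    for (nm in names(rl)) {
      r <- rl[[nm]]
      if (is.null(r)) {
        cat(sprintf("  %-32s not estimable\n", nm))
      } else {
        cat(sprintf("  %-32s slope %+.3f, R^2 = %.3f, p = %.2g, n = %d\n",
                    nm, r$slope, r$r_squared, r$p_value, r$n))
      }
    }
  }
  invisible(x)
}

#' @export
summary.barrier_analysis <- function(object, ...) {
  print(object)
  cat("\nPer-trial metrics (head):\n")
  print(utils::head(object$metrics, 10))
  invisible(object)
}

#' Plot a barrier-stepping analysis
#'
#' Two panels per animal: observed (open squares) and simulated (filled
#' circles) toe-trajectory slope against initial toe-to-barrier distance,
#' and simulated against observed slope with the identity line.
#'
#' @param x a \code{barrier_analysis}.
#' @param ... unused.
#' @export
plot.barrier_analysis <- function(x, ...) {
  animals <- unique(x$metrics$animal)
  op <- graphics::par(mfrow = c(length(animals), 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (an in animals) {
    m <- x$metrics[x$metrics$animal == an, ]
    graphics::plot(100 * m$distance, m$actual_slope, pch = 0,
                   xlab = "initial toe-to-barrier distance (cm)",
                   ylab = "toe-trajectory slope",
                   main = sprintf("animal %s", an),
                   ylim = range(c(m$actual_slope, m$simulated_slope),
                                na.rm = TRUE))
    graphics::points(100 * m$distance, m$simulated_slope, pch = 16)
    graphics::legend("topright", c("observed", "fixed-command model"),
                     pch = c(0, 16), cex = 0.8)
    rng <- range(c(m$actual_slope, m$simulated_slope), na.rm = TRUE)
    graphics::plot(m$actual_slope, m$simulated_slope, pch = 16,
                   xlim = rng, ylim = rng, xlab = "observed slope",
                   ylab = "simulated slope", main = "model vs data")
    graphics::abline(0, 1, lty = 2)
    r <- x$regressions[[an]]$simulated_vs_actual_slope
    if (!is.null(r)) graphics::abline(r$intercept, r$slope)
  }
  invisible(x)
}
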