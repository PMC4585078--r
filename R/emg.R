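#' EMG trace container
#'
#' A raw electromyogram channel: uniform time base, arbitrary units.
#' Channels of interest are the knee flexors semitendinosus (\code{"ST"})
#' and medial sartorius (\code{"Sart_m"}) and the hip flexor iliopsoas
#' (\code{"IP"}).
#'
#' @param t time vector, s (uniform).
#' @param v signal values, AU.
#' @param sample_rate Hz.
#' @param channel channel label.
#' @return object of class \code{"emg_trace"}.
#' @export
emg_trace <- function(t, v, sample_rate, channel = "ST") {
  if (length(t) != length(v)) stop("t and v lengths differ")
  if (!is.finite(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be > 0")
  structure(list(t = as.numeric(t), v = as.numeric(v),
                 sample_rate = sample_rate, channel = channel),
            class = "emg_trace")
}

#' @export
print.emg_trace <- function(x, ...) {
  cat(sprintf("EMG trace '%s': %d samples at %g Hz (%.2f s)\n",
              x$channel, length(x$v), x$sample_rate,
              length(x$v) / x$sample_rate))
  invisible(x)
}

#' Linear envelope of an EMG trace
#'
#' Full-wave rectification followed by a zero-phase 2nd-order Butterworth
#' low-pass at 50 Hz.
#'
#' @param trace an \code{\link{emg_trace}}.
#' @param cutoff low-pass cutoff, Hz.
#' @return numeric envelope series (same length as the trace).
#' @export
emg_envelope <- function(trace, cutoff = 50) {
  stopifnot(inherits(trace, "emg_trace"))
  if (trace$sample_rate <= 2 * cutoff)
    stop(sprintf("sample rate (%g Hz) must exceed twice the %g Hz cutoff",
                 trace$sample_rate, cutoff))
  zero_phase_butter(abs(trace$v), trace$sample_rate, cutoff)
}

#' Detect EMG burst onset
#'
#' A burst is declared where the envelope exceeds the baseline mean plus
#' \code{k} baseline standard deviations (baseline = first 100 ms) for at
#' least \code{persist}; the onset is then backtracked to the last sample
#' at or below baseline mean + 1 SD, so that the reported time marks the
#' beginning of the rise rather than the (amplitude-dependent) threshold
#' crossing -- without the backtrack the integration window starts late
#' and burst magnitudes are inflated.
#'
#' @param envelope envelope series (from \code{\link{emg_envelope}}).
#' @param sample_rate Hz.
#' @param baseline_window baseline duration, s.
#' @param k threshold in baseline SDs above the baseline mean.
#' @param persist required persistence, s.
#' @return onset time, s (relative to the start of the envelope).
#' @export
detect_burst_onset <- function(envelope, sample_rate, baseline_window = 0.1,
                               k = 3, persist = 0.02) {
  n <- length(envelope)
  nb <- max(2L, min(n, round(baseline_window * sample_rate)))
  base <- envelope[seq_len(nb)]
  thr <- mean(base) + k * stats::sd(base)
  np <- max(1L, round(persist * sample_rate))
  above <- envelope > thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ok <- which(runs$values & runs$lengths >= np)
  if (!length(ok)) stop("no EMG burst detected")
  cross <- starts[ok[1]]
  low <- mean(base) + stats::sd(base)
  below <- which(envelope[seq_len(cross)] <= low)
  onset <- if (length(below)) min(below[length(below)] + 1L, cross) else cross
  (onset - 1L) / sample_rate
}

#' EMG burst magnitude
#'
#' Trapezoidal integral of the envelope over a fixed window (150 ms by
#' default) from burst onset; the standard burst-size statistic.
#'
#' @param envelope envelope series.
#' @param sample_rate Hz.
#' @param onset burst onset, s (e.g. from \code{\link{detect_burst_onset}}).
#' @param window integration window, s.
#' @return magnitude, AU s.
#' @export
burst_magnitude <- function(envelope, sample_rate, onset, window = 0.150) {
  if (window <= 0) stop("window must be > 0")
  i0 <- 1L + round(onset * sample_rate)
  i1 <- 1L + round((onset + window) * sample_rate)
  if (i0 < 1L || i1 > length(envelope))
    stop("integration window extends beyond the trace")
  seg <- envelope[i0:i1]
  dt <- 1 / sample_rate
  dt * (sum(seg) - (seg[1] + seg[length(seg)]) / 2)
}
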