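#' Motion-capture trial container
#'
#' One stepping trial: 2-D marker time series at the capture rate (60 Hz
#' by default) for the iliac crest, hip, ankle, paw joint and toe tip (the
#' knee is reconstructed later by triangulation), optional EMG channels,
#' the barrier position and trial metadata.  Internally everything is SI
#' (m, s); trial files on disk use cm.
#'
#' @param trial_id label.
#' @param t time vector, s.
#' @param markers named list of n x 2 matrices (m, world frame):
#'   \code{iliac_crest}, \code{hip}, \code{ankle}, \code{paw_joint},
#'   \code{toe}.
#' @param sample_rate capture rate, Hz.
#' @param barrier_x world x of the (remembered) barrier, m.
#' @param emg optional named list of \code{\link{emg_trace}} objects.
#' @param meta list of metadata (e.g. \code{distance}, the nominal initial
#'   toe-to-barrier distance in m, and \code{animal}).
#' @return object of class \code{"leg_trial"}.
#' @export
leg_trial <- function(trial_id, t, markers, sample_rate = 60,
                      barrier_x = NA_real_, emg = list(), meta = list()) {
  need <- c("iliac_crest", "hip", "ankle", "paw_joint", "toe")
  if (!all(need %in% names(markers)))
    stop("markers must include: ", paste(need, collapse = ", "))
  if ("knee" %in% names(markers))
    stop("the knee is not a raw marker; it is reconstructed by triangulation")
  n <- length(t)
  markers <- lapply(markers[need], function(mm) {
    mm <- as.matrix(mm)
    if (nrow(mm) != n || ncol(mm) != 2L)
      stop("every marker series must be an n x 2 matrix on the trial time base")
    colnames(mm) <- c("x", "y")
    mm
  })
  if (!is.finite(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be > 0")
  structure(list(trial_id = trial_id, t = as.numeric(t), markers = markers,
                 sample_rate = sample_rate, barrier_x = barrier_x,
                 emg = emg, meta = meta),
            class = "leg_trial")
}

#' @export
print.leg_trial <- function(x, ...) {
  cat(sprintf("Trial '%s': %d frames at %g Hz (%.2f s), %d EMG channel(s)\n",
              x$trial_id, length(x$t), x$sample_rate,
              length(x$t) / x$sample_rate, length(x$emg)))
  if (!is.null(x$meta$distance))
    cat(sprintf("  nominal toe-to-barrier distance: %.1f cm\n",
                100 * x$meta$distance))
  invisible(x)
}

#' Read and write trials as JSON
#'
#' The on-disk schema stores marker coordinates in cm (converted to SI on
#' read): a top-level object with \code{trial_id}, \code{sample_rate_hz},
#' \code{barrier_x_cm}, \code{t_s}, \code{markers} (name -> \code{x_cm},
#' \code{y_cm} arrays), \code{emg} (channel -> \code{sample_rate_hz},
#' \code{t_s}, \code{value_au}) and \code{meta}.
#'
#' @param trial a \code{\link{leg_trial}}.
#' @param path file path.
#' @return \code{read_trial_json} returns a \code{leg_trial}.
#' @export
write_trial_json <- function(trial, path) {
  obj <- list(
    trial_id = trial$trial_id,
    sample_rate_hz = trial$sample_rate,
    barrier_x_cm = trial$barrier_x * 100,
    t_s = trial$t,
    markers = lapply(trial$markers, function(mm)
      list(x_cm = mm[, 1] * 100, y_cm = mm[, 2] * 100)),
    emg = lapply(trial$emg, function(e)
      list(sample_rate_hz = e$sample_rate, t_s = e$t, value_au = e$v)),
    meta = trial$meta
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trial_json
#' @export
read_trial_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  markers <- lapply(obj$markers, function(mm)
    cbind(x = mm$x_cm / 100, y = mm$y_cm / 100))
  emg <- list()
  if (length(obj$emg))
    emg <- mapply(function(e, ch)
      emg_trace(e$t_s, e$value_au, e$sample_rate_hz, channel = ch),
      obj$emg, names(obj$emg), SIMPLIFY = FALSE)
  leg_trial(obj$trial_id, obj$t_s, markers,
            sample_rate = obj$sample_rate_hz,
            barrier_x = obj$barrier_x_cm / 100,
            emg = emg, meta = as.list(obj$meta))
}

#' Read and write trial markers as long-form CSV
#'
#' Columns \code{time_s, marker, x_cm, y_cm}; metadata travels in comment
#' header lines (\code{# key: value}).  EMG, if any, goes to a companion
#' file \code{<path>_emg.csv} with columns \code{t_s, value_au, channel}.
#'
#' @inheritParams write_trial_json
#' @return \code{read_trial_csv} returns a \code{leg_trial}.
#' @export
write_trial_csv <- function(trial, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# trial_id: %s", trial$trial_id), con)
  writeLines(sprintf("# sample_rate_hz: %g", trial$sample_rate), con)
  writeLines(sprintf("# barrier_x_cm: %.6f", trial$barrier_x * 100), con)
  if (!is.null(trial$meta$distance))
    writeLines(sprintf("# distance_cm: %.6f", trial$meta$distance * 100), con)
  if (!is.null(trial$meta$animal))
    writeLines(sprintf("# animal: %s", trial$meta$animal), con)
  df <- do.call(rbind, lapply(names(trial$markers), function(nm)
    data.frame(time_s = trial$t, marker = nm,
               x_cm = trial$markers[[nm]][, 1] * 100,
               y_cm = trial$markers[[nm]][, 2] * 100)))
  utils::write.csv(df, con, row.names = FALSE)
  if (length(trial$emg)) {
    edf <- do.call(rbind, lapply(trial$emg, function(e)
      data.frame(t_s = e$t, value_au = e$v, channel = e$channel)))
    utils::write.csv(edf, paste0(sub("\\.csv$", "", path), "_emg.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  hdr <- readLines(path, n = 20)
  hdr <- hdr[startsWith(hdr, "#")]
  get <- function(key) {
    ln <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    trimws(sub(sprintf("^# %s:", key), "", ln[1]))
  }
  df <- utils::read.csv(path, comment.char = "#")
  markers <- lapply(split(df, df$marker), function(d)
    cbind(x = d$x_cm / 100, y = d$y_cm / 100))
  t <- df$time_s[df$marker == df$marker[1]]
  meta <- list()
  if (!is.null(get("distance_cm")))
    meta$distance <- as.numeric(get("distance_cm")) / 100
  if (!is.null(get("animal"))) meta$animal <- get("animal")
  emg <- list()
  emg_path <- paste0(sub("\\.csv$", "", path), "_emg.csv")
  if (file.exists(emg_path)) {
    edf <- utils::read.csv(emg_path)
    emg <- lapply(split(edf, edf$channel), function(d)
      emg_trace(d$t_s, d$value_au,
                sample_rate = 1 / stats::median(diff(d$t_s)),
                channel = d$channel[1]))
  }
  leg_trial(get("trial_id"), t, markers,
            sample_rate = as.numeric(get("sample_rate_hz")),
            barrier_x = as.numeric(get("barrier_x_cm")) / 100,
            emg = emg, meta = meta)
}
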