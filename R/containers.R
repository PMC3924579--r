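#' Construct a single-channel field-potential signal
#'
#' Light S3 container for one channel's sample series.
#'
#' @param x numeric sample series (conventionally microvolts).
#' @param fs sampling rate in Hz.
#' @param channel channel label.
#' @param units amplitude units, default `"uV"`.
#' @return an object of class `lfp_signal` with fields `x`, `fs`, `channel`,
#'   `units`.
#' @export
lfp_signal <- function(x, fs, channel = "ch1", units = "uV") {
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop_config("fs must be a positive number")
  if (!is.numeric(x) || length(x) < 1) stop_config("signal must be a non-empty numeric vector")
  structure(list(x = as.numeric(x), fs = fs, channel = channel, units = units),
            class = "lfp_signal")
}

#' @export
print.lfp_signal <- function(x, ...) {
  cat(sprintf("<lfp_signal> channel %s: %d samples @ %g Hz (%.2f s), %s\n",
              x$channel, length(x$x), x$fs, length(x$x) / x$fs, x$units))
  invisible(x)
}

#' @export
length.lfp_signal <- function(x) length(x$x)

as_signal <- function(x, fs, channel = "ch1") {
  if (inherits(x, "lfp_signal")) x else lfp_signal(x, fs, channel)
}

signal_duration <- function(sig) length(sig$x) / sig$fs

#' Canonical 8-site montage
#'
#' Channel roles: left/right dorsal hippocampus (`LHC`, `RHC`), left/right
#' medial prefrontal cortex (`LmPFC`, `RmPFC`), and four epidural screws over
#' frontal and parietal bone (`LFS`, `RFS`, `LPS`, `RPS`).  The eight
#' canonical electrode pairs used for phase-locking analysis are the
#' inter-hippocampal, inter-mPFC, the two ipsilateral hippocampus-mPFC pairs,
#' the inter-hemispheric frontal and parietal screw pairs, and the two
#' associational (frontal-parietal) screw pairs.
#'
#' @return an object of class `montage`: list with `channels` (character) and
#'   `pairs` (data.frame with columns `a`, `b`, `pair`).
#' @export
canonical_montage <- function() {
  pairs <- data.frame(
    a = c("LHC", "LmPFC", "LHC",   "RHC",   "LFS", "LPS", "LFS", "RFS"),
    b = c("RHC", "RmPFC", "LmPFC", "RmPFC", "RFS", "RPS", "LPS", "RPS"),
    stringsAsFactors = FALSE
  )
  pairs$pair <- paste(pairs$a, pairs$b, sep = "-")
  structure(list(
    channels = c("LHC", "RHC", "LmPFC", "RmPFC", "LFS", "RFS", "LPS", "RPS"),
    pairs = pairs
  ), class = "montage")
}

#' Construct a multi-channel recording
#'
#' @param signals named list of [lfp_signal()] objects sharing one sampling
#'   rate and length.
#' @param group,treatment,session_id session metadata.
#' @return object of class `recording`.
#' @export
recording <- function(signals, group = NA_character_, treatment = NA_character_,
                      session_id = NA_character_) {
  if (length(signals) == 0) stop_config("recording needs at least one channel")
  if (is.null(names(signals)) || any(names(signals) == "")) {
    stop_config("signals must be a named list")
  }
  fs <- unique(vapply(signals, function(s) s$fs, numeric(1)))
  ns <- unique(vapply(signals, function(s) length(s$x), numeric(1)))
  if (length(fs) != 1 || length(ns) != 1) {
    stop_config("all channels must share one sampling rate and length")
  }
  structure(list(signals = signals, fs = fs, n = ns,
                 meta = list(group = group, treatment = treatment,
                             session_id = session_id)),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              length(x$signals), x$n, x$fs, x$n / x$fs))
  cat("  channels:", paste(names(x$signals), collapse = ", "), "\n")
  m <- x$meta
  cat(sprintf("  group=%s treatment=%s session=%s\n", m$group, m$treatment, m$session_id))
  invisible(x)
}

# ---- text I/O --------------------------------------------------------------

#' Write / read a recording as long-form CSV (t_s, channel, value_uV)
#'
#' @param rec a [recording()].
#' @param path output file.
#' @export
write_recording_csv <- function(rec, path) {
  t_s <- (seq_len(rec$n) - 1) / rec$fs
  df <- do.call(rbind, lapply(names(rec$signals), function(ch) {
    data.frame(t_s = t_s, channel = ch, value_uV = rec$signals[[ch]]$x)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @param fs sampling rate of the stored series (inferred from timestamps when
#'   `NULL`).
#' @export
read_recording_csv <- function(path, fs = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_s", "channel", "value_uV")
  if (!all(need %in% names(df))) stop_data("recording CSV must have columns %s",
                                           paste(need, collapse = ", "))
  chans <- unique(df$channel)
  first <- df[df$channel == chans[1], ]
  if (is.null(fs)) {
    dt <- diff(first$t_s[seq_len(min(100, nrow(first)))])
    fs <- 1 / median(dt)
  }
  sigs <- lapply(chans, function(ch) lfp_signal(df$value_uV[df$channel == ch], fs, ch))
  names(sigs) <- chans
  recording(sigs)
}

#' Write ground truth (or any list of plain fields) as JSON
#' @param truth list, typically the `truth` element returned by a generator.
#' @param path output file.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' Write a trajectory as CSV (t_s, x_cm, y_cm, arena_angle_deg)
#' @param traj data.frame from [gen_trajectory()].
#' @param path output file.
#' @export
write_trajectory_csv <- function(traj, path) {
  write.csv(traj[, c("t_s", "x_cm", "y_cm", "arena_angle_deg")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_s", "x_cm", "y_cm")
  if (!all(need %in% names(df))) stop_data("trajectory CSV must have columns %s",
                                           paste(need, collapse = ", "))
  df
}
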