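#' Spike-wave detector parameters
#'
#' Defaults follow the classifier design: Morlet continuous wavelet transform
#' at scales 5-50 (step 5) on a 1000-Hz working rate, corresponding to
#' pseudo-frequencies 16-160 Hz; 50-ms sliding variance summed over scales
#' with 50-ms smoothing; threshold at `median + threshold_k * MAD`; gaps
#' shorter than 0.75 s filled; segments shorter than 1 s removed; segments
#' kept only when at least half of their inter-spike intervals fall in the
#' 2-10 Hz range.
#'
#' @param scales Morlet wavelet scales (samples at the working rate).
#' @param fs_work working sampling rate, Hz; inputs at an integer multiple are
#'   decimated down to it.
#' @param var_window_ms sliding-variance window, ms.
#' @param smooth_ms moving-average smoothing of the summed profile, ms.
#' @param threshold_k robust threshold multiplier on the MAD.
#' @param max_gap_s gaps between candidate segments shorter than this are
#'   filled.
#' @param min_len_s segments shorter than this are removed.
#' @param isi_lo_hz,isi_hi_hz admissible inter-spike rate range, Hz.
#' @param isi_frac minimum fraction of inter-spike intervals inside the range.
#' @param sat_max_ms saturation runs shorter than this are tolerated, ms.
#' @param sat_frac_max channel excluded when more than this fraction of time
#'   is lost to long saturations.
#' @param peak_prom_frac local-maxima prominence floor, as a fraction of the
#'   detection threshold.
#' @export
detector_params <- function(scales = seq(5, 50, by = 5), fs_work = 1000,
                            var_window_ms = 50, smooth_ms = 50,
                            threshold_k = 6, max_gap_s = 0.75, min_len_s = 1.0,
                            isi_lo_hz = 2, isi_hi_hz = 10, isi_frac = 0.5,
                            sat_max_ms = 50, sat_frac_max = 0.05,
                            peak_prom_frac = 0.05) {
  if (any(scales <= 0) || var_window_ms <= 0 || smooth_ms <= 0 ||
      threshold_k <= 0 || max_gap_s <= 0 || min_len_s <= 0) {
    stop_config("detector parameters must be positive")
  }
  if (isi_lo_hz >= isi_hi_hz) stop_config("isi_lo_hz must be < isi_hi_hz")
  structure(list(scales = scales, fs_work = fs_work,
                 var_window_ms = var_window_ms, smooth_ms = smooth_ms,
                 threshold_k = threshold_k, max_gap_s = max_gap_s,
                 min_len_s = min_len_s, isi_lo_hz = isi_lo_hz,
                 isi_hi_hz = isi_hi_hz, isi_frac = isi_frac,
                 sat_max_ms = sat_max_ms, sat_frac_max = sat_frac_max,
                 peak_prom_frac = peak_prom_frac),
            class = "detector_params")
}

#' Screen a channel for amplifier saturation
#'
#' Marks runs of samples at or beyond the rail.  Brief runs (shorter than
#' `sat_max_ms`) are tolerated so large spike components clipped by the
#' amplifier are not lost; longer runs are excluded from analyzed time.  The
#' channel fails screening when the excluded fraction exceeds `sat_frac_max`.
#'
#' @param sig an [lfp_signal()].
#' @param rail saturation rail, microvolts (> 0).
#' @param p a [detector_params()].
#' @return list: `sat_mask` (logical, all saturated samples),
#'   `excluded` (interval matrix, seconds), `analyzed_s`, `channel_ok`.
#' @export
screen_saturation <- function(sig, rail, p = detector_params()) {
  stopifnot(inherits(sig, "lfp_signal"))
  if (!is.numeric(rail) || rail <= 0) stop_config("rail must be > 0")
  x <- sig$x
  fs <- sig$fs
  sat <- abs(x) >= rail
  runs <- logical_runs(sat)
  min_run <- ceiling(p$sat_max_ms / 1000 * fs)
  long <- runs[runs[, 2] - runs[, 1] + 1L >= min_run, , drop = FALSE]
  excluded <- if (nrow(long) == 0) empty_intervals() else {
    as_intervals((long[, 1] - 1) / fs, long[, 2] / fs)
  }
  total_s <- length(x) / fs
  excl_s <- sum(interval_lengths(excluded))
  list(sat_mask = sat, excluded = excluded,
       analyzed_s = total_s - excl_s,
       channel_ok = (excl_s / total_s) <= p$sat_frac_max)
}

# real Morlet wavelet transform: convolution of the signal with
# psi((t-b)/a) / sqrt(a), psi(t) = exp(-t^2/2) cos(5 t).  Center frequency
# 5/(2*pi) ~ 0.8 so pseudo-frequency = 0.8125 * fs / scale, mapping scales
# 50..5 at 1000 Hz to roughly 16-160 Hz.
cwt_morlet_scale <- function(x, a) {
  half <- ceiling(4 * a)
  tt <- (-half):half
  k <- exp(-(tt / a)^2 / 2) * cos(5 * tt / a) / sqrt(a)
  m <- length(k)
  n <- length(x)
  # reflect the edges so the convolution has no zero-padding ramps
  pad <- min(half, n - 1)
  xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(n - pad):(n - 1)]))
  np <- length(xp)
  L <- stats::nextn(np + m - 1, 2)
  y <- Re(fft(fft(c(xp, numeric(L - np))) * fft(c(k, numeric(L - m))), inverse = TRUE)) / L
  off <- (m - 1) %/% 2 + pad
  y[(off + 1):(off + n)]
}

#' Summed wavelet sliding-variance profile
#'
#' The detection statistic: the signal is decimated to the working rate,
#' transformed with the Morlet continuous wavelet transform at each configured
#' scale, the sliding variance (50-ms window) is computed per scale, variances
#' are summed across scales, and the summed profile is smoothed with a 50-ms
#' moving average.  Spike-wave complexes, whose sharp spikes carry broadband
#' 16-160 Hz energy, stand out strongly in this statistic.
#'
#' @param sig an [lfp_signal()].
#' @param p a [detector_params()].
#' @return object of class `variance_profile`: list with `v` (profile),
#'   `fs` (working rate), `n_src` (original length), `decim` (factor).
#' @export
variance_profile <- function(sig, p = detector_params()) {
  stopifnot(inherits(sig, "lfp_signal"))
  x <- sig$x - mean(sig$x)              # detection is DC-invariant
  fs <- sig$fs
  decim <- 1L
  if (fs > p$fs_work) {
    if (fs %% p$fs_work != 0) stop_config("fs (%g) must be a multiple of fs_work (%g)", fs, p$fs_work)
    decim <- as.integer(fs / p$fs_work)
    x <- signal::decimate(x, decim, ftype = "fir")
    fs <- p$fs_work
  }
  wvar <- round(p$var_window_ms / 1000 * fs)
  if (length(x) < wvar) stop_data("insufficient-data: signal shorter than the variance window")
  prof <- numeric(length(x))
  for (a in p$scales) {
    cw <- cwt_morlet_scale(x, a)
    prof <- prof + run_var(cw, wvar)
  }
  prof <- run_mean(prof, round(p$smooth_ms / 1000 * fs))
  structure(list(v = prof, fs = fs, n_src = length(sig$x), decim = decim),
            class = "variance_profile")
}

#' @export
plot.variance_profile <- function(x, ...) {
  t <- (seq_along(x$v) - 1) / x$fs
  plot(t, x$v, type = "l", xlab = "time (s)", ylab = "summed variance", ...)
  invisible(x)
}

# robust threshold over analyzed samples
profile_threshold <- function(profile, p, analyzed = NULL) {
  v <- profile$v
  if (!is.null(analyzed)) v <- v[analyzed]
  median(v) + p$threshold_k * mad(v)
}

#' Mark candidate segments by threshold crossing
#'
#' Candidates are maximal runs where the variance profile exceeds
#' `median + threshold_k * MAD`, both statistics taken over analyzed
#' (non-excluded) time.
#'
#' @param profile a [variance_profile()].
#' @param p a [detector_params()].
#' @param excluded interval matrix of excluded time (seconds), e.g. from
#'   [screen_saturation()].
#' @return interval matrix (seconds) with attribute `threshold`.
#' @export
threshold_segments <- function(profile, p = detector_params(), excluded = NULL) {
  stopifnot(inherits(profile, "variance_profile"))
  fs <- profile$fs
  n <- length(profile$v)
  analyzed <- rep(TRUE, n)
  if (!is.null(excluded) && nrow(excluded) > 0) {
    for (j in seq_len(nrow(excluded))) {
      i0 <- max(1L, floor(excluded[j, 1] * fs) + 1L)
      i1 <- min(n, ceiling(excluded[j, 2] * fs))
      if (i1 >= i0) analyzed[i0:i1] <- FALSE
    }
  }
  thr <- profile_threshold(profile, p, analyzed)
  runs <- logical_runs(profile$v > thr & analyzed)
  iv <- if (nrow(runs) == 0) empty_intervals() else {
    as_intervals((runs[, 1] - 1) / fs, runs[, 2] / fs)
  }
  attr(iv, "threshold") <- thr
  iv
}

#' Fill short gaps, then drop short segments
#'
#' Gaps between consecutive candidate segments shorter than `max_gap_s` are
#' filled first (merging the segments); afterwards all segments shorter than
#' `min_len_s` are removed.
#'
#' @param intervals sorted disjoint interval matrix (seconds).
#' @param p a [detector_params()].
#' @return filtered interval matrix; attributes preserved.
#' @export
merge_and_filter <- function(intervals, p = detector_params()) {
  thr <- attr(intervals, "threshold")
  if (nrow(intervals) == 0) return(intervals)
  if (is.unsorted(intervals[, 1]) ||
      (nrow(intervals) > 1 && any(intervals[-1, 1] < intervals[-nrow(intervals), 2]))) {
    stop_data("intervals must be sorted and disjoint")
  }
  # gap filling
  out_s <- intervals[1, 1]; out_e <- intervals[1, 2]
  if (nrow(intervals) > 1) {
    for (j in 2:nrow(intervals)) {
      gap <- intervals[j, 1] - out_e[length(out_e)]
      if (gap < p$max_gap_s) {
        out_e[length(out_e)] <- intervals[j, 2]
      } else {
        out_s <- c(out_s, intervals[j, 1])
        out_e <- c(out_e, intervals[j, 2])
      }
    }
  }
  iv <- as_intervals(out_s, out_e)
  iv <- iv[interval_lengths(iv) >= p$min_len_s, , drop = FALSE]
  attr(iv, "threshold") <- thr
  iv
}

#' Keep segments with periodic spiking
#'
#' Local maxima of the smoothed variance profile inside each segment define
#' spike times (maxima must clear a prominence floor of
#' `peak_prom_frac * threshold` so sample-level ripples do not fragment the
#' inter-spike intervals).  A segment is kept when at least `isi_frac` of its
#' inter-spike intervals corresponds to rates in `[isi_lo_hz, isi_hi_hz]`
#' (boundaries inclusive); segments with fewer than three maxima cannot form
#' interval statistics and are rejected.
#'
#' @param profile a [variance_profile()].
#' @param intervals interval matrix from [merge_and_filter()].
#' @param p a [detector_params()].
#' @param channel channel label stamped on the events.
#' @return `swd_events` data.frame: `channel`, `start_s`, `end_s`, `n_spikes`,
#'   with a list column `spike_times_s`.
#' @export
periodicity_filter <- function(profile, intervals, p = detector_params(),
                               channel = "ch1") {
  stopifnot(inherits(profile, "variance_profile"))
  thr <- attr(intervals, "threshold")
  if (is.null(thr)) thr <- profile_threshold(profile, p)
  fs <- profile$fs
  keep <- list()
  if (nrow(intervals) > 0) {
    for (j in seq_len(nrow(intervals))) {
      i0 <- max(1L, floor(intervals[j, 1] * fs) + 1L)
      i1 <- min(length(profile$v), ceiling(intervals[j, 2] * fs))
      seg <- profile$v[i0:i1]
      ex <- local_extrema(seg)
      mx <- ex$max_idx
      if (length(mx) > 0) {
        prom <- vapply(mx, function(i) peak_prominence(seg, i), numeric(1))
        mx <- mx[prom >= p$peak_prom_frac * thr]
      }
      if (length(mx) < 3) next
      st <- (i0 + mx - 2) / fs            # spike times in session seconds
      isi <- diff(st)
      rate <- 1 / isi
      frac <- mean(rate >= p$isi_lo_hz & rate <= p$isi_hi_hz)
      if (frac >= p$isi_frac) {
        keep[[length(keep) + 1]] <- list(start = intervals[j, 1], end = intervals[j, 2],
                                         spikes = st)
      }
    }
  }
  events <- data.frame(
    channel = rep(channel, length(keep)),
    start_s = vapply(keep, function(e) e$start, numeric(1)),
    end_s = vapply(keep, function(e) e$end, numeric(1)),
    n_spikes = vapply(keep, function(e) length(e$spikes), integer(1)),
    stringsAsFactors = FALSE
  )
  events$spike_times_s <- I(lapply(keep, function(e) e$spikes))
  class(events) <- c("swd_events", "data.frame")
  events
}

#' Detect spike-wave events in one channel
#'
#' Runs the full classifier: saturation screening (when a rail is given),
#' wavelet variance profile, robust thresholding, gap filling and length
#' filtering, and the periodicity test.
#'
#' @param sig an [lfp_signal()].
#' @param p a [detector_params()].
#' @param rail optional saturation rail (microvolts); when given, long
#'   saturation runs are excluded from analyzed time and from detection.
#' @return `swd_events` data.frame with attributes `analyzed` (analyzed-time
#'   interval matrix), `threshold`.
#' @export
detect_swd <- function(sig, p = detector_params(), rail = NULL) {
  stopifnot(inherits(sig, "lfp_signal"))
  total_s <- signal_duration(sig)
  excluded <- empty_intervals()
  if (!is.null(rail)) {
    scr <- screen_saturation(sig, rail, p)
    if (!scr$channel_ok) stop_data("channel %s excluded: substantial saturation", sig$channel)
    excluded <- scr$excluded
  }
  prof <- variance_profile(sig, p)
  cand <- threshold_segments(prof, p, excluded = excluded)
  segs <- merge_and_filter(cand, p)
  events <- periodicity_filter(prof, segs, p, channel = sig$channel)
  attr(events, "analyzed") <- interval_complement(excluded, total_s)
  attr(events, "threshold") <- attr(cand, "threshold")
  events
}

#' Fraction of analyzed time occupied by detected events
#'
#' Total event duration divided by total analyzed time; event time falling
#' inside excluded (non-analyzed) intervals is not counted.
#'
#' @param events `swd_events` (or any data.frame with `start_s`, `end_s`).
#' @param analyzed either total analyzed seconds (scalar) or an interval
#'   matrix of analyzed time.
#' @return fraction in `[0, 1]`.
#' @export
prevalence <- function(events, analyzed) {
  if (is.matrix(analyzed)) {
    tot <- sum(interval_lengths(analyzed))
    if (tot <= 0) stop_data("degenerate: zero analyzed time")
    if (nrow(events) == 0) return(0)
    ev <- sum(vapply(seq_len(nrow(events)), function(j) {
      interval_overlap(events$start_s[j], events$end_s[j], analyzed)
    }, numeric(1)))
  } else {
    tot <- analyzed
    if (!is.numeric(tot) || tot <= 0) stop_data("degenerate: zero analyzed time")
    if (nrow(events) == 0) return(0)
    ev <- sum(events$end_s - events$start_s)
  }
  min(1, ev / tot)
}

#' Sweep the detection threshold against synthetic ground truth
#'
#' Tuning harness: generates seeded single-channel sessions with scheduled
#' spike-wave trains, runs the detector across a grid of `threshold_k`, and
#' reports event-level sensitivity (ground-truth trains overlapped by a
#' detection at Jaccard >= 0.5) and false-detection prevalence on event-free
#' time.
#'
#' @param k_grid threshold multipliers to try.
#' @param n_sessions sessions per grid point.
#' @param cfg base [gen_config()] for the sessions.
#' @param swd a [swd_spec()] for the injected trains.
#' @param p base [detector_params()] (threshold_k is overridden).
#' @return data.frame: `threshold_k`, `sensitivity`, `false_prevalence`.
#' @export
tune_threshold_k <- function(k_grid = c(4, 6, 8, 10), n_sessions = 5,
                             cfg = gen_config(duration_s = 120),
                             swd = swd_spec(), p = detector_params()) {
  out <- lapply(k_grid, function(k) {
    pk <- p; pk$threshold_k <- k
    hits <- 0L; total <- 0L; fp_s <- 0; free_s <- 0
    for (s in seq_len(n_sessions)) {
      cfg_s <- cfg; cfg_s$seed <- derive_seed(cfg$seed, 1000 + s)
      sched <- data.frame(start_s = c(20, 55, 90), dur_s = c(2, 3, 2))
      sched <- sched[sched$start_s + sched$dur_s < cfg_s$duration_s, , drop = FALSE]
      ses <- gen_session(cfg_s, couplings = list(), swd = swd, schedule = sched,
                         swd_channels = "LFS")
      ev <- detect_swd(ses$rec$signals$LFS, pk)
      sc <- score_detection(ev, ses$truth$events, cfg_s$duration_s)
      hits <- hits + sc$hits; total <- total + sc$n_truth
      fp_s <- fp_s + sc$false_s; free_s <- free_s + sc$free_s
    }
    data.frame(threshold_k = k, sensitivity = hits / max(1L, total),
               false_prevalence = fp_s / max(free_s, 1e-9))
  })
  do.call(rbind, out)
}

# event-level scoring of detections against ground-truth intervals
score_detection <- function(events, truth_iv, duration_s, jaccard_min = 0.5) {
  n_truth <- nrow(truth_iv)
  hits <- 0L
  if (n_truth > 0 && nrow(events) > 0) {
    for (j in seq_len(n_truth)) {
      jac <- vapply(seq_len(nrow(events)), function(i) {
        interval_jaccard(truth_iv[j, ], c(events$start_s[i], events$end_s[i]))
      }, numeric(1))
      if (any(jac >= jaccard_min)) hits <- hits + 1L
    }
  }
  # detected time outside any true event
  false_s <- 0
  if (nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      inside <- interval_overlap(events$start_s[i], events$end_s[i], truth_iv)
      false_s <- false_s + (events$end_s[i] - events$start_s[i]) - inside
    }
  }
  free_s <- duration_s - sum(interval_lengths(truth_iv))
  list(hits = hits, n_truth = n_truth, false_s = false_s, free_s = free_s)
}

#' Export detected events
#' @param events `swd_events`.
#' @param path output CSV path.
#' @export
write_events_csv <- function(events, path) {
  write.csv(events[, c("channel", "start_s", "end_s", "n_spikes")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
write_events_json <- function(events, path) {
  lst <- lapply(seq_len(nrow(events)), function(i) {
    list(channel = events$channel[i], start_s = events$start_s[i],
         end_s = events$end_s[i], spike_times_s = events$spike_times_s[[i]])
  })
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
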