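#' Feature-extraction parameters
#'
#' @param lowpass_hz cut-off of the zero-phase low-pass applied before
#'   extraction (removes high-frequency components that would fragment local
#'   extrema).
#' @param amp_min_uV minimum spike amplitude: peak voltage minus the higher of
#'   the two flanking minima must reach this value.
#' @param width_min_ms,width_max_ms admissible spike width range.  The printed
#'   acceptance rule is a minimum width of 50 ms; a maximum is exposed for
#'   users who prefer the more common convention of bounding sharp transients
#'   from above, and defaults to `Inf` (disabled).
#' @param seq_lo_hz,seq_hi_hz spike-sequence rate range: inter-spike times are
#'   reported as within-sequence only when the rate of successive spikes falls
#'   in this range.
#' @export
feature_params <- function(lowpass_hz = 100, amp_min_uV = 400,
                           width_min_ms = 50, width_max_ms = Inf,
                           seq_lo_hz = 5, seq_hi_hz = 13) {
  structure(list(lowpass_hz = lowpass_hz, amp_min_uV = amp_min_uV,
                 width_min_ms = width_min_ms, width_max_ms = width_max_ms,
                 seq_lo_hz = seq_lo_hz, seq_hi_hz = seq_hi_hz),
            class = "feature_params")
}

#' Low-pass a marked segment before feature extraction
#'
#' Zero-phase FIR low-pass at `lowpass_hz` (default 100 Hz).  DC is preserved.
#'
#' @param segment an [lfp_signal()].
#' @param p a [feature_params()].
#' @return filtered [lfp_signal()].
#' @export
preprocess_segment <- function(segment, p = feature_params()) {
  stopifnot(inherits(segment, "lfp_signal"))
  fs <- segment$fs
  # generous order keeps passband gain flat to ~0.1% (filtfilt squares the
  # response, so droop would otherwise double)
  ord <- max(10L, 2L * (round(7.5 * fs / p$lowpass_hz) %/% 2L))
  if (length(segment$x) <= 3 * ord) {
    ord <- 2L * (floor((length(segment$x) - 1) / 3) %/% 2L)
    if (ord < 4) stop_data("insufficient-data: segment shorter than the filter warm-up")
  }
  b <- signal::fir1(ord, p$lowpass_hz / (fs / 2), type = "low")
  segment$x <- signal::filtfilt(b, segment$x)
  segment
}

# width of a peak at a horizontal level, searching outward from the peak and
# bounded by the flanking minima; crossings located by linear interpolation
width_at_level <- function(x, fs, i_peak, i_pre, i_post, level) {
  # left crossing
  tl <- (i_pre - 1) / fs
  for (i in seq(i_peak, i_pre + 1L)) {
    if (x[i - 1] <= level && x[i] > level) {
      frac <- (level - x[i - 1]) / (x[i] - x[i - 1])
      tl <- (i - 2 + frac) / fs
      break
    }
  }
  tr <- (i_post - 1) / fs
  for (i in seq(i_peak, i_post - 1L)) {
    if (x[i + 1] <= level && x[i] > level) {
      frac <- (x[i] - level) / (x[i] - x[i + 1])
      tr <- (i - 1 + frac) / fs
      break
    }
  }
  c(tl, tr)
}

#' Detect spike components in a spike-wave segment
#'
#' Finds local maxima in the (already low-pass filtered) segment, locates the
#' preceding and following local minima of each, and keeps the maxima that
#' satisfy both the amplitude criterion (peak minus the *higher* flanking
#' minimum at least `amp_min_uV`) and the width criterion (spike width,
#' measured at the level of the higher-voltage flanking minimum, within
#' `[width_min_ms, width_max_ms]`).
#'
#' @param segment an [lfp_signal()], low-pass filtered by
#'   [preprocess_segment()].
#' @param p a [feature_params()].
#' @return data.frame of spike components: `peak_idx`, `peak_time_s`,
#'   `peak_uV`, `pre_min_idx`, `pre_min_t`, `pre_min_uV`, `post_min_idx`,
#'   `post_min_t`, `post_min_uV`, `width_ms`.
#' @export
find_spikes <- function(segment, p = feature_params()) {
  stopifnot(inherits(segment, "lfp_signal"))
  x <- segment$x
  fs <- segment$fs
  ex <- local_extrema(x)
  empty <- data.frame(peak_idx = integer(0), peak_time_s = numeric(0),
                      peak_uV = numeric(0), pre_min_idx = integer(0),
                      pre_min_t = numeric(0), pre_min_uV = numeric(0),
                      post_min_idx = integer(0), post_min_t = numeric(0),
                      post_min_uV = numeric(0), width_ms = numeric(0))
  if (length(ex$max_idx) == 0 || length(ex$min_idx) == 0) return(empty)
  rows <- list()
  for (im in ex$max_idx) {
    pre <- ex$min_idx[ex$min_idx < im]
    post <- ex$min_idx[ex$min_idx > im]
    if (length(pre) == 0 || length(post) == 0) next
    i_pre <- max(pre); i_post <- min(post)
    level <- max(x[i_pre], x[i_post])
    if (x[im] - level < p$amp_min_uV) next
    wd <- width_at_level(x, fs, im, i_pre, i_post, level)
    width_ms <- (wd[2] - wd[1]) * 1000
    if (width_ms < p$width_min_ms || width_ms > p$width_max_ms) next
    rows[[length(rows) + 1]] <- data.frame(
      peak_idx = im, peak_time_s = (im - 1) / fs, peak_uV = x[im],
      pre_min_idx = i_pre, pre_min_t = (i_pre - 1) / fs, pre_min_uV = x[i_pre],
      post_min_idx = i_post, post_min_t = (i_post - 1) / fs, post_min_uV = x[i_post],
      width_ms = width_ms)
  }
  if (length(rows) == 0) return(empty)
  do.call(rbind, rows)
}

#' Per-cycle morphology features
#'
#' For each detected spike: spike duration (the width at the level of the
#' higher-voltage flanking minimum), spike-to-valley voltage (peak minus the
#' following minimum), inter-spike time to the next spike (flagged as
#' within-sequence when the implied rate is in the 5-13 Hz range), wave
#' duration (following minimum of this spike to the preceding minimum of the
#' next), and wave energy (sum of squared amplitudes over the wave-duration
#' samples).
#'
#' @param segment the low-pass filtered [lfp_signal()].
#' @param spikes data.frame from [find_spikes()].
#' @param p a [feature_params()] (sequence rate range).
#' @return data.frame, one row per spike: `spike_time_s`,
#'   `spike_duration_ms`, `spike_to_valley_uV`, `inter_spike_ms`,
#'   `in_sequence`, `wave_duration_ms`, `wave_energy`; inter-spike/wave
#'   features are `NA` for the last (or a lone) spike.
#' @export
extract_features <- function(segment, spikes, p = feature_params()) {
  stopifnot(inherits(segment, "lfp_signal"))
  x <- segment$x
  fs <- segment$fs
  n <- nrow(spikes)
  if (n == 0) {
    return(data.frame(spike_time_s = numeric(0), spike_duration_ms = numeric(0),
                      spike_to_valley_uV = numeric(0), inter_spike_ms = numeric(0),
                      in_sequence = logical(0), wave_duration_ms = numeric(0),
                      wave_energy = numeric(0)))
  }
  if (is.unsorted(spikes$peak_idx)) stop_data("spikes must be sorted by time")
  inter <- rep(NA_real_, n)
  in_seq <- rep(NA, n)
  wave_dur <- rep(NA_real_, n)
  wave_en <- rep(NA_real_, n)
  if (n > 1) {
    for (k in seq_len(n - 1)) {
      isi_ms <- (spikes$peak_time_s[k + 1] - spikes$peak_time_s[k]) * 1000
      inter[k] <- isi_ms
      rate <- 1000 / isi_ms
      in_seq[k] <- rate >= p$seq_lo_hz && rate <= p$seq_hi_hz
      i0 <- spikes$post_min_idx[k]
      i1 <- spikes$pre_min_idx[k + 1]
      if (i1 > i0) {
        wave_dur[k] <- (i1 - i0) / fs * 1000
        wave_en[k] <- sum(x[i0:i1]^2)
      }
    }
  }
  data.frame(spike_time_s = spikes$peak_time_s,
             spike_duration_ms = spikes$width_ms,
             spike_to_valley_uV = spikes$peak_uV - spikes$post_min_uV,
             inter_spike_ms = inter,
             in_sequence = in_seq,
             wave_duration_ms = wave_dur,
             wave_energy = wave_en)
}

#' Extract features over marked intervals of a channel
#'
#' Convenience wrapper: cuts the marked intervals out of a channel, low-pass
#' filters each, detects spikes and extracts per-cycle features.
#'
#' @param sig an [lfp_signal()].
#' @param intervals interval matrix or data.frame with `start_s`, `end_s`
#'   (e.g. read from a manual-marking file).
#' @param p a [feature_params()].
#' @return combined feature data.frame with an `event` index column.
#' @export
features_for_intervals <- function(sig, intervals, p = feature_params()) {
  stopifnot(inherits(sig, "lfp_signal"))
  if (is.data.frame(intervals)) intervals <- as_intervals(intervals$start_s, intervals$end_s)
  out <- NULL
  for (j in seq_len(nrow(intervals))) {
    i0 <- max(1L, floor(intervals[j, 1] * sig$fs) + 1L)
    i1 <- min(length(sig$x), ceiling(intervals[j, 2] * sig$fs))
    seg <- lfp_signal(sig$x[i0:i1], sig$fs, sig$channel)
    seg <- preprocess_segment(seg, p)
    sp <- find_spikes(seg, p)
    ft <- extract_features(seg, sp, p)
    if (nrow(ft) > 0) {
      ft$spike_time_s <- ft$spike_time_s + (i0 - 1) / sig$fs
      ft$event <- j
      out <- rbind(out, ft)
    }
  }
  if (is.null(out)) {
    out <- extract_features(lfp_signal(0, sig$fs), find_spikes(lfp_signal(c(0, 1, 0), sig$fs)))
    out$event <- integer(0)
  }
  out
}

#' Build a balanced feature probability distribution
#'
#' Draws a constant-size subsample of events (without replacement) from each
#' animal so every subject contributes equally, pools the values, and returns
#' a histogram normalized to unit sum.
#'
#' @param values_by_animal named list of numeric feature vectors, one per
#'   animal.
#' @param subsample_n events drawn per animal; every animal must have at
#'   least this many (otherwise an error names the offender).
#' @param breaks histogram bin edges (passed to [cut()]); default 20 equal
#'   bins over the pooled range.
#' @param seed RNG seed for the subsampling.
#' @return list of class `feature_distribution`: `bin_left`, `bin_right`,
#'   `probability` (sums to 1), `subsample_n`, `pooled` (the subsampled
#'   values).
#' @export
build_distribution <- function(values_by_animal, subsample_n, breaks = 20,
                               seed = 1L) {
  if (is.null(names(values_by_animal))) stop_config("values_by_animal must be named")
  sizes <- vapply(values_by_animal, length, integer(1))
  short <- names(sizes)[sizes < subsample_n]
  if (length(short) > 0) {
    stop_data("animal(s) %s have fewer than %d events", paste(short, collapse = ", "),
              subsample_n)
  }
  pooled <- with_seed(seed, {
    unlist(lapply(values_by_animal, function(v) sample(v, subsample_n)), use.names = FALSE)
  })
  if (length(breaks) == 1) {
    rg <- range(pooled)
    if (diff(rg) == 0) rg <- rg + c(-0.5, 0.5)
    breaks <- seq(rg[1], rg[2], length.out = breaks + 1)
  }
  h <- hist(pooled, breaks = breaks, plot = FALSE)
  structure(list(bin_left = head(h$breaks, -1), bin_right = tail(h$breaks, -1),
                 probability = h$counts / sum(h$counts),
                 subsample_n = subsample_n, pooled = pooled),
            class = "feature_distribution")
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' `D = sup |ECDF_A - ECDF_B|` with the asymptotic p-value, as used to compare
#' feature distributions between groups.
#'
#' @param samples_a,samples_b numeric samples (non-empty).
#' @return list with `D`, `p`, `n_a`, `n_b`.
#' @export
ks_compare <- function(samples_a, samples_b) {
  if (length(samples_a) == 0 || length(samples_b) == 0) stop_data("empty sample")
  kt <- suppressWarnings(ks.test(samples_a, samples_b, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value),
       n_a = length(samples_a), n_b = length(samples_b))
}

#' Export per-cycle features / distributions as CSV
#' @param features data.frame from [extract_features()].
#' @param path output file.
#' @export
write_features_csv <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @param dist a `feature_distribution`.
#' @export
write_distribution_csv <- function(dist, path) {
  write.csv(data.frame(bin_left = dist$bin_left, bin_right = dist$bin_right,
                       probability = dist$probability), path, row.names = FALSE)
  invisible(path)
}

#' Read a marked-interval file
#'
#' CSV with columns `channel`, `start_s`, `end_s` and optionally `source`
#' (one of `manual`, `auto`, `truth`).
#'
#' @param path CSV path.
#' @export
read_intervals_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("channel", "start_s", "end_s")
  if (!all(need %in% names(df))) stop_data("interval CSV must have columns %s",
                                           paste(need, collapse = ", "))
  df
}
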