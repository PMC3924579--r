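# analytic signal via frequency-domain Hilbert transform
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# 5-Hz sub-band tiling of a canonical band, from lo upward
band_subbands <- function(lo, hi) {
  starts <- seq(lo, hi - 5, by = 5)
  cbind(lo = starts, hi = starts + 5)
}

#' Band-limited instantaneous phase
#'
#' Filters the signal with a zero-phase (forward-backward) windowed-sinc FIR
#' band-pass and takes the angle of the analytic signal (Hilbert transform).
#' The filter bank granularity is fixed at 5 Hz: `hi - lo` must equal 5 and
#' the band must lie within 0-100 Hz.  The FIR order is `3 * fs / lo` rounded
#' to even (capped at a third of the signal length); one filter length at each
#' edge is flagged unreliable and excluded from downstream phase-locking sums.
#'
#' @param sig an [lfp_signal()] or numeric vector (then `fs` required).
#' @param lo,hi band edges, Hz (`hi - lo` must be 5).
#' @param fs sampling rate for plain numeric input.
#' @return object of class `phase_series`: list with `phase` (radians, wrapped
#'   to (-pi, pi]), `fs`, `band`, `edge` (samples to discard at each end).
#' @export
narrowband_phase <- function(sig, lo, hi, fs = NULL) {
  if (inherits(sig, "lfp_signal")) { x <- sig$x; fs <- sig$fs } else x <- as.numeric(sig)
  if (is.null(fs)) stop_config("fs required for plain numeric input")
  if (lo <= 0 || hi > 100) stop_data("unsupported-band: [%g, %g] outside 0-100 Hz", lo, hi)
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  if (abs((hi - lo) - 5) > 1e-9) {
    stop_data("unsupported-band: filter bank granularity is 5 Hz (got %g)", hi - lo)
  }
  n <- length(x)
  ord <- round(3 * fs / lo)
  ord <- min(ord, floor((n - 1) / 3))
  ord <- max(2L, 2L * (ord %/% 2L))
  b <- signal::fir1(ord, c(lo, hi) / (fs / 2), type = "pass")
  y <- signal::filtfilt(b, x)
  ph <- Arg(analytic_signal(y))
  structure(list(phase = ph, fs = fs, band = c(lo, hi), edge = ord),
            class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("<phase_series> %d samples @ %g Hz, band %g-%g Hz, edge %d\n",
              length(x$phase), x$fs, x$band[1], x$band[2], x$edge))
  invisible(x)
}

#' Phase-locking value between two phase series
#'
#' Evaluates `PLV = (1/N) | sum_n exp(i * theta_n) |` with
#' `theta = phase1 - phase2`.  For `phase_series` inputs the larger of the two
#' edge allowances is discarded from both ends before the sum; plain numeric
#' phase vectors are used as-is.
#'
#' @param phase1,phase2 `phase_series` objects or numeric phase vectors
#'   (radians) of equal length.
#' @param mask optional logical vector (full series length) restricting the
#'   samples entering the sum.
#' @return PLV in `[0, 1]`.
#' @export
plv <- function(phase1, phase2, mask = NULL) {
  p1 <- if (inherits(phase1, "phase_series")) phase1$phase else as.numeric(phase1)
  p2 <- if (inherits(phase2, "phase_series")) phase2$phase else as.numeric(phase2)
  if (length(p1) != length(p2)) stop_data("phase series lengths differ (%d vs %d)",
                                          length(p1), length(p2))
  if (inherits(phase1, "phase_series") && inherits(phase2, "phase_series") &&
      !isTRUE(all.equal(phase1$band, phase2$band))) {
    stop_data("phase series come from different bands")
  }
  keep <- rep(TRUE, length(p1))
  edge <- max(if (inherits(phase1, "phase_series")) phase1$edge else 0L,
              if (inherits(phase2, "phase_series")) phase2$edge else 0L)
  if (edge > 0 && length(p1) > 2 * edge) {
    keep[seq_len(edge)] <- FALSE
    keep[(length(p1) - edge + 1):length(p1)] <- FALSE
  }
  if (!is.null(mask)) keep <- keep & mask
  n <- sum(keep)
  if (n == 0) stop_data("empty-input: no samples left for the PLV sum")
  Mod(mean(exp(1i * (p1[keep] - p2[keep]))))
}

#' Band-averaged phase-locking value
#'
#' Computes the PLV in each 5-Hz sub-band tiling the requested canonical band
#' (theta 5-10/10-15; beta 20-25/25-30; slow gamma 30-35 ... 50-55; fast gamma
#' 65-70 ... 95-100) and returns their arithmetic mean.
#'
#' @param sig1,sig2 [lfp_signal()]s or numeric vectors (then `fs` required).
#' @param band band name from [canonical_bands()] or a list/row with
#'   `lo`, `hi`.
#' @param fs sampling rate for plain numeric input.
#' @param mask optional logical sample mask passed to [plv()].
#' @export
band_plv <- function(sig1, sig2, band = "theta", fs = NULL, mask = NULL) {
  if (is.character(band)) {
    bands <- canonical_bands()
    if (!band %in% bands$name) stop_config("unknown band '%s'", band)
    band <- bands[bands$name == band, ]
  }
  sb <- band_subbands(band$lo, band$hi)
  vals <- vapply(seq_len(nrow(sb)), function(i) {
    p1 <- narrowband_phase(sig1, sb[i, 1], sb[i, 2], fs = fs)
    p2 <- narrowband_phase(sig2, sb[i, 1], sb[i, 2], fs = fs)
    plv(p1, p2, mask = mask)
  }, numeric(1))
  mean(vals)
}

#' Session synchrony vector (8 pairs x 4 bands)
#'
#' Computes the band-averaged PLV for every canonical electrode pair and
#' frequency band of a session, yielding the 32-dimensional synchrony vector
#' that summarizes the session.  Channels are optionally screened for
#' saturation first; a missing or excluded channel aborts with an error naming
#' it.
#'
#' @param rec a [recording()] containing all montage channels.
#' @param montage a [canonical_montage()].
#' @param bands band set (default [canonical_bands()]).
#' @param rail optional saturation rail (microvolts); when given, channels are
#'   screened with [screen_saturation()] and excluded channels abort.
#' @param mask optional logical sample mask for the PLV sums.
#' @return object of class `sync_vector`: data.frame with columns `pair`,
#'   `band`, `plv` (32 rows) plus session metadata attributes.
#' @export
session_sync_vector <- function(rec, montage = canonical_montage(),
                                bands = canonical_bands(), rail = NULL,
                                mask = NULL) {
  stopifnot(inherits(rec, "recording"))
  missing_ch <- setdiff(montage$channels, names(rec$signals))
  if (length(missing_ch) > 0) {
    stop_data("incomplete-montage: missing channel(s) %s", paste(missing_ch, collapse = ", "))
  }
  if (!is.null(rail)) {
    for (ch in montage$channels) {
      scr <- screen_saturation(rec$signals[[ch]], rail)
      if (!scr$channel_ok) stop_data("incomplete-montage: channel %s excluded by saturation screening", ch)
    }
  }
  # phase series per channel per sub-band, computed once
  sub_list <- lapply(seq_len(nrow(bands)), function(i) band_subbands(bands$lo[i], bands$hi[i]))
  phases <- list()
  for (ch in montage$channels) {
    for (bi in seq_len(nrow(bands))) {
      sb <- sub_list[[bi]]
      for (si in seq_len(nrow(sb))) {
        key <- sprintf("%s|%g", ch, sb[si, 1])
        if (is.null(phases[[key]])) {
          phases[[key]] <- narrowband_phase(rec$signals[[ch]], sb[si, 1], sb[si, 2])
        }
      }
    }
  }
  rows <- list()
  for (pi in seq_len(nrow(montage$pairs))) {
    a <- montage$pairs$a[pi]; b <- montage$pairs$b[pi]
    for (bi in seq_len(nrow(bands))) {
      sb <- sub_list[[bi]]
      vals <- vapply(seq_len(nrow(sb)), function(si) {
        plv(phases[[sprintf("%s|%g", a, sb[si, 1])]],
            phases[[sprintf("%s|%g", b, sb[si, 1])]], mask = mask)
      }, numeric(1))
      rows[[length(rows) + 1]] <- data.frame(pair = montage$pairs$pair[pi],
                                             band = bands$name[bi],
                                             plv = mean(vals),
                                             stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "meta") <- rec$meta
  class(out) <- c("sync_vector", "data.frame")
  out
}

#' Flatten sync vectors to one wide row per session
#'
#' @param sv a `sync_vector` from [session_sync_vector()].
#' @return named numeric vector of length 32, names `pair.band`.
#' @export
sync_vector_values <- function(sv) {
  v <- sv$plv
  names(v) <- paste(sv$pair, sv$band, sep = ".")
  v
}

#' Export sync vectors as CSV
#' @param sv a `sync_vector`.
#' @param path output file.
#' @export
write_sync_csv <- function(sv, path) {
  meta <- attr(sv, "meta")
  df <- data.frame(session_id = meta$session_id %||% NA, group = meta$group %||% NA,
                   treatment = meta$treatment %||% NA, sv, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
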