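#' Canonical frequency bands
#'
#' Band definitions shared by all modules: theta 5-15 Hz, beta 20-30 Hz
#' (chosen to exclude the strong second theta harmonic), slow gamma 30-55 Hz,
#' fast gamma 65-100 Hz (excluding the 60-Hz mains region).  Band edges are
#' half-open `[lo, hi)` so shared edges are never double counted.  The delta
#' band (0-3 Hz) is provided for completeness but flagged `attenuated`: it is
#' unreliable under the hardware DC-removal filter and never enters synchrony
#' vectors.
#'
#' @param include_delta also return the attenuated delta band.
#' @return data.frame with columns `name`, `lo`, `hi`, `attenuated`.
#' @export
canonical_bands <- function(include_delta = FALSE) {
  b <- data.frame(
    name = c("theta", "beta", "slow_gamma", "fast_gamma"),
    lo = c(5, 20, 30, 65),
    hi = c(15, 30, 55, 100),
    attenuated = FALSE,
    stringsAsFactors = FALSE
  )
  if (include_delta) {
    b <- rbind(data.frame(name = "delta", lo = 0.5, hi = 3, attenuated = TRUE), b)
  }
  b
}

#' Normalize a signal to unit RMS
#'
#' Divides the series by its root-mean-square value, removing
#' electrode-specific amplitude differences (impedance, exact placement)
#' before spectral comparison across channels and animals.
#'
#' @param sig an [lfp_signal()] or numeric vector.
#' @return the same type of object with RMS exactly 1.
#' @export
rms_normalize <- function(sig) {
  x <- if (inherits(sig, "lfp_signal")) sig$x else sig
  r <- sqrt(mean(x^2))
  if (!is.finite(r) || r == 0) stop_data("degenerate-signal: RMS is zero")
  if (inherits(sig, "lfp_signal")) {
    sig$x <- x / r
    sig$units <- "rms"
    sig
  } else {
    x / r
  }
}

#' Welch power spectral density over non-overlapping windows
#'
#' The signal is cut into consecutive non-overlapping windows of `window_s`
#' seconds (a trailing partial window is discarded); each window is
#' mean-subtracted, Hamming-tapered, and periodogram-transformed; the
#' one-sided periodograms are averaged.  The scaling is such that the summed
#' PSD of a unit-RMS signal is approximately 1 (Parseval).
#'
#' @param sig an [lfp_signal()] or numeric vector (then `fs` is required).
#' @param window_s analysis window length, seconds (default 5).
#' @param fs sampling rate when `sig` is a plain vector.
#' @return object of class `psd`: list with `freqs` (Hz), `power`, `window_s`,
#'   `n_windows`, `fs`.
#' @export
compute_psd <- function(sig, window_s = 5, fs = NULL) {
  if (inherits(sig, "lfp_signal")) { x <- sig$x; fs <- sig$fs } else x <- as.numeric(sig)
  if (is.null(fs)) stop_config("fs required for plain numeric input")
  nw <- round(window_s * fs)
  n_win <- floor(length(x) / nw)
  if (n_win < 1) stop_data("insufficient-data: signal shorter than one %g s window", window_s)
  ham <- 0.54 - 0.46 * cos(2 * pi * seq(0, nw - 1) / (nw - 1))
  u <- sum(ham^2)                       # window power for Parseval scaling
  nfreq <- floor(nw / 2) + 1
  acc <- numeric(nfreq)
  for (k in seq_len(n_win)) {
    seg <- x[((k - 1) * nw + 1):(k * nw)]
    seg <- (seg - mean(seg)) * ham
    X <- fft(seg)
    p <- Mod(X[seq_len(nfreq)])^2 / (nw * u)
    # one-sided: double everything except DC (and Nyquist for even nw)
    if (nw %% 2 == 0) p[2:(nfreq - 1)] <- 2 * p[2:(nfreq - 1)] else p[2:nfreq] <- 2 * p[2:nfreq]
    acc <- acc + p
  }
  structure(list(freqs = seq(0, nfreq - 1) * (fs / nw), power = acc / n_win,
                 window_s = window_s, n_windows = n_win, fs = fs),
            class = "psd")
}

#' @export
print.psd <- function(x, ...) {
  cat(sprintf("<psd> %d bins, 0-%g Hz, %g s windows x %d\n",
              length(x$freqs), max(x$freqs), x$window_s, x$n_windows))
  invisible(x)
}

#' @export
plot.psd <- function(x, log = "y", xlim = c(0, 120), ...) {
  sel <- x$freqs >= xlim[1] & x$freqs <= xlim[2] & x$power > 0
  plot(x$freqs[sel], x$power[sel], type = "l", log = log,
       xlab = "frequency (Hz)", ylab = "power", ...)
  invisible(x)
}

#' Interpolate the PSD across the mains-noise region
#'
#' Replaces all bins strictly inside `(lo, hi)` (default 58-62 Hz) by linear
#' interpolation between the bin values at the interval edges, removing the
#' 60-Hz line peak while leaving every other bin untouched.
#'
#' @param psd a `psd` object from [compute_psd()].
#' @param lo,hi interval bounds, Hz.
#' @return modified `psd`.
#' @export
interpolate_line_region <- function(psd, lo = 58, hi = 62) {
  stopifnot(inherits(psd, "psd"))
  if (lo >= hi) stop_config("invalid-range: lo must be < hi")
  f <- psd$freqs
  if (lo < min(f) || hi > max(f)) stop_config("interpolation range outside the frequency grid")
  inner <- which(f > lo & f < hi)
  if (length(inner) == 0) return(psd)
  i_lo <- max(which(f <= lo))
  i_hi <- min(which(f >= hi))
  psd$power[inner] <- approx(x = f[c(i_lo, i_hi)], y = psd$power[c(i_lo, i_hi)],
                             xout = f[inner])$y
  psd
}

#' Normalize a PSD to unit total power
#'
#' @param psd a `psd` object.
#' @return `psd` whose power sums to exactly 1.
#' @export
normalize_psd <- function(psd) {
  stopifnot(inherits(psd, "psd"))
  s <- sum(psd$power)
  if (!is.finite(s) || s <= 0) stop_data("degenerate PSD: total power is zero")
  psd$power <- psd$power / s
  psd
}

#' Fraction of PSD power in a band
#'
#' Sums power over bins with `lo <= f < hi` and divides by the total, so the
#' result is a fraction in `[0, 1]` whether or not the PSD was normalized.
#'
#' @param psd a `psd` object.
#' @param band either a row of [canonical_bands()] (list/data.frame with `lo`,
#'   `hi`) or a numeric `c(lo, hi)`.
#' @export
band_fraction <- function(psd, band) {
  stopifnot(inherits(psd, "psd"))
  if (is.numeric(band)) band <- list(lo = band[1], hi = band[2])
  s <- sum(psd$power)
  if (!is.finite(s) || s <= 0) stop_data("degenerate PSD: total power is zero")
  sel <- psd$freqs >= band$lo & psd$freqs < band$hi
  sum(psd$power[sel]) / s
}

#' Export a PSD as CSV (freq_hz, power_fraction)
#' @param psd a `psd` object (normalized or not).
#' @param path output file.
#' @export
write_psd_csv <- function(psd, path) {
  s <- sum(psd$power)
  write.csv(data.frame(freq_hz = psd$freqs, power_fraction = psd$power / s),
            path, row.names = FALSE)
  invisible(path)
}
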