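#' Generator configuration
#'
#' Shared configuration for all signal generators.  Defaults emulate the
#' acquisition conditions of the recordings the pipeline targets: 2000 Hz
#' sampling after 1-500 Hz band-pass, microvolt units, and a 1/f background.
#'
#' @param fs sampling rate, Hz.
#' @param duration_s session duration, seconds.
#' @param seed integer RNG seed; identical configurations produce
#'   bit-identical output.
#' @param background_exponent spectral slope of the 1/f^a background
#'   (0 = white noise).
#' @param background_rms target RMS amplitude of the background, microvolts.
#' @param line_amp amplitude of additive 60-Hz mains contamination, microvolts.
#' @param sat_rail_uV amplifier saturation rail; samples are hard-clipped at
#'   +/- this value (`Inf` disables clipping).
#' @return list of class `gen_config`.
#' @export
gen_config <- function(fs = 2000, duration_s = 60, seed = 1L,
                       background_exponent = 1, background_rms = 50,
                       line_amp = 0, sat_rail_uV = Inf) {
  if (!is.numeric(fs) || fs <= 0) stop_config("fs must be > 0")
  if (!is.numeric(duration_s) || duration_s <= 0) stop_config("duration_s must be > 0")
  if (background_rms < 0) stop_config("background_rms must be >= 0")
  structure(list(fs = fs, duration_s = duration_s, seed = as.integer(seed),
                 background_exponent = background_exponent,
                 background_rms = background_rms, line_amp = line_amp,
                 sat_rail_uV = sat_rail_uV),
            class = "gen_config")
}

#' Coupling specification for an oscillator pair
#'
#' Describes a band-limited oscillation shared by two channels whose
#' instantaneous phase difference is von Mises distributed.  The ground-truth
#' expected phase-locking value is the Bessel ratio `I1(kappa)/I0(kappa)`
#' (see [plv_expected()]).
#'
#' @param band_center oscillation center frequency, Hz.
#' @param band_width approximate spectral width of the oscillation, Hz.
#' @param kappa von Mises concentration of the phase difference (>= 0;
#'   0 = uniform, large = locked).
#' @param mean_lag mean phase lag, radians.
#' @param amp oscillation amplitude, microvolts.
#' @export
coupling_spec <- function(band_center = 7.5, band_width = 3, kappa = 2,
                          mean_lag = 0, amp = 400) {
  if (kappa < 0) stop_config("kappa must be >= 0")
  if (band_width <= 0) stop_config("band_width must be > 0")
  structure(list(band_center = band_center, band_width = band_width,
                 kappa = kappa, mean_lag = mean_lag, amp = amp),
            class = "coupling_spec")
}

#' Spike-wave train specification
#'
#' Morphology parameters for a synthetic spike-wave discharge train.  Each
#' cycle consists of a shallow pre-spike notch, a sharp raised-cosine spike,
#' and a slower negative wave whose trough is the "valley" that follows the
#' spike.
#'
#' @param cycle_freq cycle rate, Hz (rodent SWDs are ~2-10 Hz; default 6).
#' @param n_cycles number of spike-wave cycles.
#' @param spike_amp spike peak amplitude, microvolts.
#' @param spike_width_ms width of the raised-cosine spike, ms.
#' @param wave_amp depth of the wave trough (valley), microvolts (positive
#'   number; the trough sits at `-wave_amp`).
#' @param jitter_ms Gaussian SD of per-cycle spike-time jitter, ms.
#' @param notch_ms width of the shallow dip preceding each spike, ms.
#' @export
swd_spec <- function(cycle_freq = 6, n_cycles = 12, spike_amp = 800,
                     spike_width_ms = 60, wave_amp = 150, jitter_ms = 0,
                     notch_ms = 30) {
  if (cycle_freq <= 0) stop_config("cycle_freq must be > 0")
  if (n_cycles < 1) stop_config("n_cycles must be >= 1")
  period_ms <- 1000 / cycle_freq
  if (spike_width_ms + notch_ms >= period_ms) {
    stop_config("spike_width_ms + notch_ms (%g ms) must be shorter than the cycle period (%g ms)",
                spike_width_ms + notch_ms, period_ms)
  }
  structure(list(cycle_freq = cycle_freq, n_cycles = as.integer(n_cycles),
                 spike_amp = spike_amp, spike_width_ms = spike_width_ms,
                 wave_amp = wave_amp, jitter_ms = jitter_ms,
                 notch_ms = notch_ms),
            class = "swd_spec")
}

#' Expected phase-locking value of a von Mises phase difference
#'
#' For a phase difference distributed von Mises with concentration `kappa`,
#' the population PLV is `I1(kappa)/I0(kappa)` (ratio of modified Bessel
#' functions of the first kind).
#'
#' @param kappa concentration parameter (>= 0); vectorized.
#' @return expected PLV in `[0, 1)`.
#' @export
plv_expected <- function(kappa) {
  out <- numeric(length(kappa))
  big <- kappa > 1e5
  # asymptotic expansion for large concentration
  out[big] <- 1 - 1 / (2 * kappa[big])
  out[!big] <- ifelse(kappa[!big] == 0, 0,
                      besselI(kappa[!big], 1, expon.scaled = TRUE) /
                        besselI(kappa[!big], 0, expon.scaled = TRUE))
  pmin(out, 1)
}

# quantile function of the von Mises distribution centered at 0, by numeric
# inversion of the CDF on a fine grid; u in [0, 1)
vonmises_quantile <- function(u, kappa) {
  if (kappa == 0) return((u - 0.5) * 2 * pi)
  if (kappa > 50) {
    # wrapped-normal limit, sd = 1/sqrt(kappa)
    q <- qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12), sd = 1 / sqrt(kappa))
    return(pmin(pmax(q, -pi), pi))
  }
  th <- seq(-pi, pi, length.out = 4096)
  dens <- exp(kappa * (cos(th) - 1))
  cdf <- cumsum(dens)
  cdf <- (cdf - cdf[1]) / (cdf[length(cdf)] - cdf[1])
  approx(cdf, th, xout = u, rule = 2, ties = "ordered")$y
}

# ---------------------------------------------------------------------------

#' Generate 1/f background noise
#'
#' White Gaussian noise is spectrally shaped in the frequency domain with
#' amplitude proportional to `f^(-background_exponent/2)` so its power
#' spectrum follows `f^(-background_exponent)`, then rescaled to the exact
#' target RMS.  Deterministic given `(cfg, seed)`.
#'
#' @param cfg a [gen_config()].
#' @return an [lfp_signal()].
#' @export
gen_background <- function(cfg) {
  stopifnot(inherits(cfg, "gen_config"))
  gen_background_seeded(cfg, cfg$seed)
}

gen_background_seeded <- function(cfg, seed, channel = "bg") {
  n <- round(cfg$fs * cfg$duration_s)
  x <- with_seed(seed, {
    w <- rnorm(n)
    if (cfg$background_exponent != 0) {
      W <- fft(w)
      f <- c(0, seq_len(n - 1)) * (cfg$fs / n)
      f <- pmin(f, cfg$fs - f)             # two-sided frequency axis
      shape <- ifelse(f > 0, f^(-cfg$background_exponent / 2), 0)
      w <- Re(fft(W * shape, inverse = TRUE) / n)
    }
    w
  })
  x <- x - mean(x)
  r <- sqrt(mean(x^2))
  if (r > 0 && cfg$background_rms > 0) x <- x * (cfg$background_rms / r) else x <- x * 0
  lfp_signal(x, cfg$fs, channel)
}

#' Generate a pair of coupled band-limited oscillators
#'
#' Both channels carry the same frequency-modulated carrier confined to the
#' requested band; channel 2 is phase-shifted by a slowly sweeping offset
#' whose marginal distribution is exactly von Mises(`mean_lag`, `kappa`).  The
#' offset sweeps the full von Mises quantile range once per `sweep_s`, so over
#' whole sweeps the time-average of `exp(i * offset)` equals the Bessel-ratio
#' population PLV, giving a sharp ground truth for PLV estimators.  Each
#' channel additionally receives independent 1/f background noise per `cfg`.
#'
#' @param cfg a [gen_config()].
#' @param spec a [coupling_spec()].
#' @param sweep_s period of the quantile sweep, seconds.
#' @return list with `sig1`, `sig2` ([lfp_signal()]s) and `truth` (list with
#'   `expected_plv`, `kappa`, `mean_lag`, `band`).
#' @export
gen_coupled_pair <- function(cfg, spec, sweep_s = 2.5) {
  stopifnot(inherits(cfg, "gen_config"), inherits(spec, "coupling_spec"))
  if (spec$band_center <= 0 || spec$band_center >= cfg$fs / 2) {
    stop_config("band_center must lie in (0, fs/2)")
  }
  n <- round(cfg$fs * cfg$duration_s)
  osc <- gen_oscillation_pair_seeded(cfg, spec, cfg$seed, sweep_s)
  bg1 <- gen_background_seeded(cfg, derive_seed(cfg$seed, 1))$x
  bg2 <- gen_background_seeded(cfg, derive_seed(cfg$seed, 2))$x
  truth <- list(expected_plv = plv_expected(spec$kappa), kappa = spec$kappa,
                mean_lag = spec$mean_lag,
                band = c(spec$band_center - spec$band_width / 2,
                         spec$band_center + spec$band_width / 2))
  list(sig1 = lfp_signal(osc$x1 + bg1, cfg$fs, "ch1"),
       sig2 = lfp_signal(osc$x2 + bg2, cfg$fs, "ch2"),
       truth = truth)
}

# carrier + phase-offset construction shared by gen_coupled_pair/gen_session
gen_oscillation_pair_seeded <- function(cfg, spec, seed, sweep_s = 2.5) {
  n <- round(cfg$fs * cfg$duration_s)
  t <- (seq_len(n) - 1) / cfg$fs
  with_seed(seed, {
    # frequency-modulated carrier: instantaneous frequency wanders over about
    # half the band width on a ~0.5 s timescale
    z <- run_mean(rnorm(n), round(0.5 * cfg$fs))
    sz <- sd(z)
    if (sz > 0) z <- z / sz
    finst <- spec$band_center + (spec$band_width / 4) * pmax(pmin(z, 2), -2)
    phi <- 2 * pi * cumsum(finst) / cfg$fs
    # phase offset: sweep through the von Mises quantile range; u moves
    # linearly on the circle so full sweeps hit every quantile equally
    u0 <- runif(1)
    dir <- sample(c(-1, 1), 1)
    u <- (u0 + dir * t / sweep_s) %% 1
    delta <- spec$mean_lag + vonmises_quantile(u, spec$kappa)
    list(x1 = spec$amp * cos(phi), x2 = spec$amp * cos(phi - delta))
  })
}

# ---------------------------------------------------------------------------

# closed-form spike-wave cycle pieces evaluated at sample times; all times s
# relative to the spike peak.  Returns the clean waveform for one train plus
# per-cycle ground truth.
render_swd_train <- function(spec, fs, t0 = 0, seed = NULL) {
  w <- spec$spike_width_ms / 1000
  v <- spec$notch_ms / 1000
  Tn <- 1 / spec$cycle_freq
  A <- spec$spike_amp
  W <- spec$wave_amp
  d <- 0.15 * W                          # pre-spike notch depth
  nc <- spec$n_cycles

  jit <- if (spec$jitter_ms > 0 && !is.null(seed)) {
    with_seed(seed, rnorm(nc, 0, spec$jitter_ms / 1000))
  } else if (spec$jitter_ms > 0) {
    rnorm(nc, 0, spec$jitter_ms / 1000)
  } else rep(0, nc)

  peak_t <- t0 + v + w / 2 + (seq_len(nc) - 1) * Tn + jit
  start_t <- peak_t[1] - w / 2 - v
  end_t <- peak_t[nc] + w / 2 + (Tn - w - v)   # trailing wave after last spike
  idx0 <- ceiling(start_t * fs)
  idx1 <- floor(end_t * fs)
  tt <- (idx0:idx1) / fs
  x <- numeric(length(tt))

  valley_t <- numeric(nc)
  notch_t <- peak_t - w / 2 - v / 2
  # piecewise assembly: notch, spike, wave for each cycle
  for (k in seq_len(nc)) {
    pk <- peak_t[k]
    # notch: half-sine dip 0 -> -d -> 0 over [pk - w/2 - v, pk - w/2]
    sel <- tt >= pk - w / 2 - v & tt < pk - w / 2
    x[sel] <- -d * sin(pi * (tt[sel] - (pk - w / 2 - v)) / v)
    # spike: raised cosine 0 -> A -> 0 over [pk - w/2, pk + w/2]
    sel <- tt >= pk - w / 2 & tt < pk + w / 2
    x[sel] <- A * 0.5 * (1 + cos(2 * pi * (tt[sel] - pk) / w))
    # wave: descend to -W then recover to 0 over the span to the next notch
    span_end <- if (k < nc) peak_t[k + 1] - w / 2 - v else end_t
    span <- span_end - (pk + w / 2)
    q <- 0.3 * span                      # valley delay after the spike
    valley_t[k] <- pk + w / 2 + q
    sel <- tt >= pk + w / 2 & tt < valley_t[k]
    x[sel] <- -W * sin(pi * (tt[sel] - (pk + w / 2)) / (2 * q))
    sel <- tt >= valley_t[k] & tt < span_end
    x[sel] <- -W * cos(pi * (tt[sel] - valley_t[k]) / (2 * (span - q)))
  }

  # ground-truth per-cycle features (see swd_features module for definitions)
  spike_dur <- numeric(nc)
  wave_dur <- rep(NA_real_, nc)
  wave_energy <- rep(NA_real_, nc)
  inter_spike <- rep(NA_real_, nc)
  for (k in seq_len(nc)) {
    span_end <- if (k < nc) peak_t[k + 1] - w / 2 - v else end_t
    span <- span_end - (peak_t[k] + w / 2)
    q <- 0.3 * span
    # width at the level of the higher flanking minimum (-d, the notch),
    # bounded on the left by the notch minimum, crossing the wave descent on
    # the right at -d
    right <- w / 2 + (2 * q / pi) * asin(min(1, d / W))
    spike_dur[k] <- (v / 2 + w / 2) + right
    if (k < nc) {
      inter_spike[k] <- peak_t[k + 1] - peak_t[k]
      wave_dur[k] <- notch_t[k + 1] - valley_t[k]
      sel <- tt >= valley_t[k] & tt <= notch_t[k + 1]
      wave_energy[k] <- sum(x[sel]^2)
    }
  }

  list(
    t = tt, x = x, start_s = idx0 / fs, end_s = idx1 / fs,
    truth = data.frame(
      cycle = seq_len(nc),
      spike_time_s = peak_t,
      spike_peak_uV = A,
      spike_to_valley_uV = A + W,
      spike_duration_ms = spike_dur * 1000,
      inter_spike_ms = inter_spike * 1000,
      wave_duration_ms = wave_dur * 1000,
      wave_energy = wave_energy
    )
  )
}

#' Generate a synthetic spike-wave train
#'
#' Renders `n_cycles` spike-wave cycles from a closed-form morphology: each
#' cycle is a shallow pre-spike notch, a raised-cosine spike of the given
#' width and amplitude, and a slower negative half-cosine wave whose trough
#' (`-wave_amp`) is the valley following the spike.  Ground truth records each
#' spike peak time and the per-cycle morphology features the feature extractor
#' measures.
#'
#' @param cfg a [gen_config()] (only `fs` and `seed` are used).
#' @param spec a [swd_spec()].
#' @return list with `segment` ([lfp_signal()] of the clean train) and
#'   `truth` (per-cycle data.frame).
#' @export
gen_swd_train <- function(cfg, spec) {
  stopifnot(inherits(cfg, "gen_config"), inherits(spec, "swd_spec"))
  r <- render_swd_train(spec, cfg$fs, t0 = 0, seed = cfg$seed)
  list(segment = lfp_signal(r$x, cfg$fs, "swd"), truth = r$truth)
}

# ---------------------------------------------------------------------------

#' Generate a full synthetic 8-channel session
#'
#' Assembles a [recording()] on the canonical montage: per-channel independent
#' 1/f background, band-limited coupled oscillations on requested electrode
#' pairs, spike-wave trains at scheduled times on the epidural screw channels,
#' optional 60-Hz line contamination and hard amplifier saturation.  Ground
#' truth carries the exact event intervals, per-cycle features, and per-pair
#' expected PLVs.
#'
#' @param cfg a [gen_config()].
#' @param montage a [canonical_montage()] (or compatible).
#' @param couplings named list of [coupling_spec()]s; names are montage pair
#'   labels such as `"LHC-RHC"`.
#' @param swd a [swd_spec()] describing train morphology, or `NULL` for none.
#' @param schedule data.frame with columns `start_s`, `dur_s` giving
#'   non-overlapping train start times and durations (train cycle counts are
#'   derived from `dur_s * cycle_freq`).
#' @param swd_channels channels that carry the scheduled trains (default the
#'   four epidural screws, where such activity is most prominent).
#' @return list with `rec` (a [recording()]) and `truth` (list: `events`
#'   intervals, `features` per-cycle data.frame, `expected_plv` named vector,
#'   `prevalence`).
#' @export
gen_session <- function(cfg, montage = canonical_montage(), couplings = list(),
                        swd = NULL, schedule = NULL,
                        swd_channels = c("LFS", "RFS", "LPS", "RPS")) {
  stopifnot(inherits(cfg, "gen_config"))
  n <- round(cfg$fs * cfg$duration_s)
  chans <- montage$channels
  if (length(couplings) > 0) {
    bad <- setdiff(names(couplings), montage$pairs$pair)
    if (length(bad) > 0) stop_config("unknown montage pair(s): %s", paste(bad, collapse = ", "))
  }

  # schedule validation: sorted, inside the session, non-overlapping
  events <- empty_intervals()
  if (!is.null(schedule) && nrow(schedule) > 0) {
    if (is.null(swd)) stop_config("schedule given without an swd_spec")
    schedule <- schedule[order(schedule$start_s), , drop = FALSE]
    ends <- schedule$start_s + schedule$dur_s
    if (any(schedule$start_s < 0) || any(ends > cfg$duration_s)) {
      stop_config("scheduled trains must lie within the session")
    }
    if (nrow(schedule) > 1 && any(schedule$start_s[-1] < ends[-length(ends)])) {
      stop("invalid-schedule: scheduled trains overlap", call. = FALSE)
    }
  }

  base <- lapply(seq_along(chans), function(i) {
    gen_background_seeded(cfg, derive_seed(cfg$seed, i), chans[i])$x
  })
  names(base) <- chans

  if (cfg$line_amp > 0) {
    t <- (seq_len(n) - 1) / cfg$fs
    line <- cfg$line_amp * sin(2 * pi * 60 * t)
    for (ch in chans) base[[ch]] <- base[[ch]] + line
  }

  expected_plv <- c()
  for (pname in names(couplings)) {
    spec <- couplings[[pname]]
    prow <- montage$pairs[montage$pairs$pair == pname, ]
    osc <- gen_oscillation_pair_seeded(cfg, spec, derive_seed(cfg$seed, 100 + match(pname, montage$pairs$pair)))
    base[[prow$a]] <- base[[prow$a]] + osc$x1
    base[[prow$b]] <- base[[prow$b]] + osc$x2
    expected_plv[pname] <- plv_expected(spec$kappa)
  }

  features <- NULL
  if (!is.null(schedule) && nrow(schedule) > 0) {
    ev_start <- numeric(0); ev_end <- numeric(0)
    for (j in seq_len(nrow(schedule))) {
      sp <- swd
      sp$n_cycles <- max(1L, as.integer(round(schedule$dur_s[j] * swd$cycle_freq)))
      r <- render_swd_train(sp, cfg$fs, t0 = schedule$start_s[j],
                            seed = derive_seed(cfg$seed, 200 + j))
      i0 <- round(r$start_s * cfg$fs) + 1
      ii <- i0:(i0 + length(r$x) - 1)
      ii <- ii[ii >= 1 & ii <= n]
      for (ch in swd_channels) base[[ch]][ii] <- base[[ch]][ii] + r$x[seq_along(ii)]
      ev_start <- c(ev_start, schedule$start_s[j])
      ev_end <- c(ev_end, schedule$start_s[j] + schedule$dur_s[j])
      tr <- r$truth
      tr$event <- j
      features <- rbind(features, tr)
    }
    events <- as_intervals(ev_start, ev_end)
  }

  if (is.finite(cfg$sat_rail_uV)) {
    for (ch in chans) base[[ch]] <- pmax(pmin(base[[ch]], cfg$sat_rail_uV), -cfg$sat_rail_uV)
  }

  sigs <- lapply(chans, function(ch) lfp_signal(base[[ch]], cfg$fs, ch))
  names(sigs) <- chans
  truth <- list(events = events, features = features,
                expected_plv = expected_plv,
                prevalence = sum(interval_lengths(events)) / cfg$duration_s)
  list(rec = recording(sigs, session_id = sprintf("synthetic-%d", cfg$seed)),
       truth = truth)
}

# ---------------------------------------------------------------------------

#' Generate group-structured synchrony vectors
#'
#' Draws per-group isotropic Gaussian clouds around given 32-dimensional
#' centroids, clipped to the `[0, 1]` PLV range.  Used as a fixture with known
#' group geometry for the synchrony-pattern analysis.
#'
#' @param group_centroids named list of numeric centroids (entries in
#'   `[0, 1]`, conventionally length 32 = 8 pairs x 4 bands).
#' @param noise_sd isotropic Gaussian noise SD.
#' @param n_per_group vectors per group; default 40 emulates 5 animals
#'   contributing 8 sessions each.
#' @param seed integer seed.
#' @return data.frame with a `group` column and one column per vector entry.
#' @export
gen_sync_vectors <- function(group_centroids, noise_sd = 0.05, n_per_group = 40,
                             seed = 1L) {
  if (is.null(names(group_centroids))) stop_config("group_centroids must be named")
  dims <- unique(vapply(group_centroids, length, integer(1)))
  if (length(dims) != 1) stop_config("all centroids must have equal length")
  for (g in names(group_centroids)) {
    cg <- group_centroids[[g]]
    if (any(cg < 0 | cg > 1)) stop_config("centroid entries must lie in [0, 1]")
  }
  p <- dims
  out <- with_seed(seed, {
    do.call(rbind, lapply(names(group_centroids), function(g) {
      m <- matrix(rnorm(n_per_group * p, sd = noise_sd), nrow = n_per_group)
      m <- sweep(m, 2, group_centroids[[g]], "+")
      m <- pmin(pmax(m, 0), 1)
      df <- as.data.frame(m)
      names(df) <- if (!is.null(names(group_centroids[[g]]))) {
        names(group_centroids[[g]])
      } else sprintf("v%02d", seq_len(p))
      cbind(group = g, df, stringsAsFactors = FALSE)
    }))
  })
  rownames(out) <- NULL
  out
}

#' Generate an arena trajectory
#'
#' Simulates an overhead-tracker position series on a rotating circular arena
#' (82 cm diameter).  Policies: `"random-walk"` (smooth reflected random
#' walk), `"avoider"` (random walk steered out of a room-frame sector),
#' `"stationary"` (no movement).
#'
#' @param arena_radius_cm arena radius (41 cm).
#' @param rotation_period_s arena rotation period, seconds (positive =
#'   counter-clockwise).
#' @param policy one of `"random-walk"`, `"avoider"`, `"stationary"`.
#' @param zone a list with `center_angle_deg` and `width_deg` (required for
#'   the avoider policy); see [zone_spec()].
#' @param duration_s trial duration, seconds (default 600 = 10-min trial).
#' @param fs_track tracker sampling rate, Hz.
#' @param speed_cm_s nominal movement speed.
#' @param seed integer seed.
#' @return data.frame: `t_s`, `x_cm`, `y_cm` (room frame), `arena_angle_deg`
#'   (cumulative arena rotation).
#' @export
gen_trajectory <- function(arena_radius_cm = 41, rotation_period_s = 60,
                           policy = c("random-walk", "avoider", "stationary"),
                           zone = NULL, duration_s = 600, fs_track = 30,
                           speed_cm_s = 8, seed = 1L) {
  policy <- match.arg(policy)
  if (policy == "avoider" && is.null(zone)) stop_config("avoider policy needs a zone")
  n <- round(duration_s * fs_track) + 1
  dt <- 1 / fs_track
  t <- (seq_len(n) - 1) * dt
  with_seed(seed, {
    x <- numeric(n); y <- numeric(n)
    if (policy == "stationary") {
      x[] <- arena_radius_cm / 2; y[] <- 0
    } else {
      heading <- runif(1, 0, 2 * pi)
      if (policy == "avoider") {
        # start opposite the forbidden sector
        a0 <- (zone$center_angle_deg + 180) * pi / 180
        px <- 0.5 * arena_radius_cm * cos(a0)
        py <- 0.5 * arena_radius_cm * sin(a0)
      } else {
        px <- 0; py <- 0
      }
      in_zone <- function(qx, qy) {
        ang <- atan2(qy, qx) * 180 / pi
        dang <- ((ang - zone$center_angle_deg + 180) %% 360) - 180
        abs(dang) <= zone$width_deg / 2 + 5      # 5 deg safety margin
      }
      turn <- rnorm(n, 0, 0.8)
      for (i in seq_len(n)) {
        x[i] <- px; y[i] <- py
        heading <- heading + turn[i] * sqrt(dt)
        nx <- px + speed_cm_s * dt * cos(heading)
        ny <- py + speed_cm_s * dt * sin(heading)
        if (policy == "avoider" && in_zone(nx, ny)) {
          heading <- heading + pi                # refuse the step, turn around
        } else {
          px <- nx; py <- ny
        }
        rr <- sqrt(px^2 + py^2)
        if (rr > 0.95 * arena_radius_cm) {       # reflect at the wall
          px <- px * (0.95 * arena_radius_cm) / rr
          py <- py * (0.95 * arena_radius_cm) / rr
          heading <- atan2(py, px) + pi + rnorm(1, 0, 0.3)
        }
      }
    }
    data.frame(t_s = t, x_cm = x, y_cm = y,
               arena_angle_deg = (360 * t / rotation_period_s) %% 360,
               valid = TRUE)
  })
}
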