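test_that("saturation screening tolerates brief clips and excludes long ones", {
  fs <- 2000
  clean <- lfp_signal(rnorm(10 * fs, sd = 50), fs)
  scr <- screen_saturation(clean, rail = 1000)
  expect_false(any(scr$sat_mask))
  expect_true(scr$channel_ok)
  expect_equal(nrow(scr$excluded), 0)

  # one 30-ms run: tolerated, analyzed time unchanged
  x <- rnorm(10 * fs, sd = 50)
  x[1001:(1000 + 0.03 * fs)] <- 1000
  scr30 <- screen_saturation(lfp_signal(x, fs), rail = 1000)
  expect_equal(nrow(scr30$excluded), 0)
  expect_equal(scr30$analyzed_s, 10)
  expect_true(scr30$channel_ok)

  # 10% of time in 200-ms runs: channel excluded
  y <- rnorm(10 * fs, sd = 50)
  for (k in 0:4) y[(k * 2 * fs + 1):(k * 2 * fs + 0.2 * fs)] <- 1000
  scr200 <- screen_saturation(lfp_signal(y, fs), rail = 1000)
  expect_equal(sum(neurosync:::interval_lengths(scr200$excluded)), 1.0, tolerance = 0.01)
  expect_false(scr200$channel_ok)
})

test_that("variance profile is zero for constant input and quadratic in amplitude", {
  fs <- 2000
  expect_error(variance_profile(lfp_signal(rnorm(10), fs)), "insufficient-data")
  flat <- variance_profile(lfp_signal(rep(3, 4 * fs), fs))
  expect_lt(max(flat$v), 1e-9)
  set.seed(5)
  x <- rnorm(4 * fs, sd = 20)
  p1 <- variance_profile(lfp_signal(x, fs))
  p2 <- variance_profile(lfp_signal(2 * x, fs))
  expect_equal(p2$v, 4 * p1$v, tolerance = 1e-6)
})

test_that("variance profile peaks align with injected spikes", {
  cfg <- gen_config(duration_s = 20, seed = 13, background_rms = 20)
  sched <- data.frame(start_s = 8, dur_s = 2)
  ses <- gen_session(cfg, swd = swd_spec(jitter_ms = 0), schedule = sched,
                     swd_channels = "LFS")
  prof <- variance_profile(ses$rec$signals$LFS)
  spikes <- ses$truth$features$spike_time_s
  for (st in spikes) {
    win <- prof$v[round((st - 0.025) * prof$fs):round((st + 0.025) * prof$fs)]
    expect_gt(max(win), median(prof$v) + 6 * mad(prof$v))
  }
})

test_that("threshold crossing marks exactly the elevated region", {
  prof <- boxcar_profile(3, 5)
  iv <- threshold_segments(prof)
  expect_equal(nrow(iv), 1)
  expect_equal(unname(iv[1, ]), c(3, 5), tolerance = 2 / prof$fs)
  # all-below-threshold profile yields nothing
  low <- boxcar_profile(3, 5, base = 1, high = 1)
  low$v <- low$v + rnorm(length(low$v), sd = 1e-3)
  expect_equal(nrow(threshold_segments(low)), 0)
})

test_that("gap filling and minimum-length rules follow the stated constants", {
  p <- detector_params()
  m1 <- merge_and_filter(neurosync:::as_intervals(c(0, 1.1), c(0.6, 1.7)), p)
  expect_equal(unname(m1[, 1]), 0)
  expect_equal(unname(m1[, 2]), 1.7)

  m2 <- merge_and_filter(neurosync:::as_intervals(0, 0.8), p)
  expect_equal(nrow(m2), 0)

  m3 <- merge_and_filter(neurosync:::as_intervals(c(0, 2.5), c(1.2, 4.0)), p)
  expect_equal(nrow(m3), 2)

  expect_error(merge_and_filter(neurosync:::as_intervals(c(2, 0), c(3, 1)), p),
               "sorted")
})

test_that("periodicity test keeps 2-10 Hz spiking and rejects the rest", {
  fs <- 1000
  mk_profile <- function(rate_hz, dur_s = 2, total_s = 4) {
    t <- seq_len(total_s * fs) / fs
    v <- rep(0.01, length(t))
    spikes <- seq(1, 1 + dur_s, by = 1 / rate_hz)
    for (st in spikes) v <- v + 10 * exp(-((t - st)^2) / (2 * 0.01^2))
    structure(list(v = v, fs = fs, n_src = length(t), decim = 1L),
              class = "variance_profile")
  }
  p <- detector_params()
  iv <- neurosync:::as_intervals(0.9, 3.2)
  attr(iv, "threshold") <- 1
  ev6 <- periodicity_filter(mk_profile(6), iv, p)
  expect_equal(nrow(ev6), 1)
  expect_true(all(abs(diff(ev6$spike_times_s[[1]]) - 1 / 6) < 0.02))
  ev20 <- periodicity_filter(mk_profile(20), iv, p)
  expect_equal(nrow(ev20), 0)
  ev1 <- periodicity_filter(mk_profile(1), iv, p)
  expect_equal(nrow(ev1), 0)
})

test_that("the boundary ISI fraction of exactly one half is kept", {
  # hand-constructed maxima: 4 ISIs at 6 Hz, 4 ISIs at 20 Hz -> fraction 0.5
  fs <- 1000
  t <- seq_len(6 * fs) / fs
  v <- rep(0.01, length(t))
  st <- cumsum(c(1, rep(1 / 6, 4), rep(1 / 20, 4)))
  for (s in st) v <- v + 10 * exp(-((t - s)^2) / (2 * 0.008^2))
  prof <- structure(list(v = v, fs = fs, n_src = length(t), decim = 1L),
                    class = "variance_profile")
  iv <- neurosync:::as_intervals(0.8, 2.2)
  attr(iv, "threshold") <- 1
  ev <- periodicity_filter(prof, iv, detector_params())
  expect_equal(nrow(ev), 1)
})

test_that("full detector recovers scheduled trains and stays quiet on noise", {
  cfg <- gen_config(duration_s = 120, seed = 29)
  sched <- data.frame(start_s = c(30, 70, 100), dur_s = c(2, 3, 2))
  ses <- gen_session(cfg, swd = swd_spec(spike_amp = 600), schedule = sched,
                     swd_channels = "LFS")
  ev <- detect_swd(ses$rec$signals$LFS)
  sc <- neurosync:::score_detection(ev, ses$truth$events, 120)
  expect_equal(sc$hits, 3L)
  # two trains 0.5 s apart merge into one event (gap rule)
  sched2 <- data.frame(start_s = c(30, 32.5), dur_s = c(2, 2))
  ses2 <- gen_session(cfg, swd = swd_spec(spike_amp = 600), schedule = sched2,
                      swd_channels = "LFS")
  ev2 <- detect_swd(ses2$rec$signals$LFS)
  expect_equal(nrow(ev2), 1)
  expect_lt(ev2$start_s[1], 31)
  expect_gt(ev2$end_s[1], 34)
  # DC-offset invariance
  sig_dc <- ses$rec$signals$LFS
  sig_dc$x <- sig_dc$x + 500
  ev_dc <- detect_swd(sig_dc)
  expect_equal(ev_dc$start_s, ev$start_s, tolerance = 0.05)
  # noise only
  ses0 <- gen_session(gen_config(duration_s = 120, seed = 31))
  ev0 <- detect_swd(ses0$rec$signals$LFS)
  expect_lt(prevalence(ev0, 120), 0.005)
})

test_that("prevalence arithmetic respects analyzed time", {
  ev <- data.frame(channel = "a", start_s = c(10, 50), end_s = c(13, 53))
  expect_equal(prevalence(ev, 100), 0.06)
  expect_equal(prevalence(ev[0, ], 100), 0)
  # event half inside excluded time is counted only within analyzed time
  analyzed <- neurosync:::as_intervals(c(0, 11.5), c(10, 100))
  expect_equal(prevalence(ev, analyzed), (1.5 + 3) / 98.5)
  expect_error(prevalence(ev, 0), "degenerate")
})
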