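test_that("the 100-Hz low-pass preserves slow content and kills fast content", {
  s5 <- sinusoid(5, duration_s = 4)
  f5 <- preprocess_segment(s5)
  core <- 2000:6000
  expect_lt(abs(max(f5$x[core]) - 1), 0.02)
  s150 <- sinusoid(150, duration_s = 4)
  f150 <- preprocess_segment(s150)
  expect_lt(max(abs(f150$x[core])), 10^(-20 / 20))   # > 20 dB down
  dc <- lfp_signal(rep(7, 8000) + rnorm(8000, sd = 0.01), 2000)
  expect_lt(abs(mean(preprocess_segment(dc)$x[core]) - 7), 0.05)
  expect_error(preprocess_segment(lfp_signal(rnorm(10), 2000)), "insufficient-data")
})

test_that("spike detection applies the amplitude and width criteria", {
  flat <- lfp_signal(rep(0, 4000), 2000)
  expect_equal(nrow(find_spikes(flat)), 0)
  # one 900-uV spike from the generator is found exactly once
  tr <- gen_swd_train(gen_config(seed = 2), swd_spec(n_cycles = 1, spike_amp = 900,
                                                     spike_width_ms = 60, jitter_ms = 0))
  pad <- lfp_signal(c(rep(0, 1000), tr$segment$x, rep(0, 1000)), 2000)
  sp <- find_spikes(preprocess_segment(pad))
  expect_equal(nrow(sp), 1)
  # a 300-uV spike fails the 400-uV amplitude rule
  tr3 <- gen_swd_train(gen_config(seed = 2), swd_spec(n_cycles = 1, spike_amp = 300,
                                                      wave_amp = 60, jitter_ms = 0))
  pad3 <- lfp_signal(c(rep(0, 1000), tr3$segment$x, rep(0, 1000)), 2000)
  expect_equal(nrow(find_spikes(preprocess_segment(pad3))), 0)
})

test_that("per-cycle features recover the generator's ground truth", {
  spec <- swd_spec(cycle_freq = 6, n_cycles = 12, spike_amp = 800,
                   spike_width_ms = 60, wave_amp = 150, jitter_ms = 0)
  tr <- gen_swd_train(gen_config(seed = 4), spec)
  seg <- preprocess_segment(tr$segment)
  ft <- extract_features(seg, find_spikes(seg))
  expect_equal(nrow(ft), 12)
  expect_lt(abs(median(ft$inter_spike_ms, na.rm = TRUE) - 1000 / 6), 2)
  expect_true(all(ft$in_sequence[1:11]))
  expect_lt(abs(median(ft$spike_to_valley_uV) - 950) / 950, 0.05)
  gt <- tr$truth
  expect_lt(abs(median(ft$spike_duration_ms) - median(gt$spike_duration_ms)) /
              median(gt$spike_duration_ms), 0.1)
  expect_lt(abs(median(ft$wave_duration_ms, na.rm = TRUE) -
                  median(gt$wave_duration_ms, na.rm = TRUE)) /
              median(gt$wave_duration_ms, na.rm = TRUE), 0.1)
  expect_lt(abs(median(ft$wave_energy, na.rm = TRUE) -
                  median(gt$wave_energy, na.rm = TRUE)) /
              median(gt$wave_energy, na.rm = TRUE), 0.1)
})

test_that("features scale equivariantly with amplitude", {
  spec <- swd_spec(n_cycles = 8, jitter_ms = 0)
  tr <- gen_swd_train(gen_config(seed = 6), spec)
  seg1 <- preprocess_segment(tr$segment)
  ft1 <- extract_features(seg1, find_spikes(seg1))
  seg2 <- tr$segment
  seg2$x <- seg2$x * 2
  seg2 <- preprocess_segment(seg2)
  ft2 <- extract_features(seg2, find_spikes(seg2))
  expect_equal(ft2$spike_to_valley_uV, 2 * ft1$spike_to_valley_uV, tolerance = 1e-6)
  expect_equal(ft2$wave_energy, 4 * ft1$wave_energy, tolerance = 1e-6)
  expect_equal(ft2$spike_duration_ms, ft1$spike_duration_ms, tolerance = 1e-6)
  expect_equal(ft2$inter_spike_ms, ft1$inter_spike_ms, tolerance = 1e-9)
})

test_that("balanced subsampling builds deterministic unit-sum distributions", {
  vals <- list(r1 = rnorm(20, 100, 5), r2 = rnorm(30, 110, 5))
  d <- build_distribution(vals, subsample_n = 5, seed = 3)
  expect_equal(length(d$pooled), 10)
  expect_lt(abs(sum(d$probability) - 1), 1e-9)
  d2 <- build_distribution(vals, subsample_n = 5, seed = 3)
  expect_identical(d$pooled, d2$pooled)
  expect_error(build_distribution(vals, subsample_n = 25), "r1")
})

test_that("KS statistic equals the exhaustive ECDF sup", {
  expect_equal(ks_compare(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_compare(c(0, 0, 0), c(1, 1, 1))$D, 1)
  set.seed(17)
  a <- rnorm(200)
  b <- rnorm(200, 1)
  D <- ks_compare(a, b)$D
  pts <- c(a, b)
  D_oracle <- max(abs(ecdf(a)(pts) - ecdf(b)(pts)))
  expect_lt(abs(D - D_oracle), 1e-12)
  expect_error(ks_compare(numeric(0), b), "empty")
})
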