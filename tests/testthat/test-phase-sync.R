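test_that("narrowband phase tracks frequency and quadrature lags", {
  fs <- 2000
  t <- seq_len(20 * fs) / fs
  p7 <- narrowband_phase(lfp_signal(cos(2 * pi * 7 * t), fs), 5, 10)
  core <- (p7$edge + 1):(length(p7$phase) - p7$edge)
  slope <- unname(coef(lm(signal::unwrap(p7$phase[core]) ~ t[core]))[2]) / (2 * pi)
  expect_lt(abs(slope - 7) / 7, 0.01)
  pc <- narrowband_phase(lfp_signal(cos(2 * pi * 7 * t), fs), 5, 10)
  ps <- narrowband_phase(lfp_signal(sin(2 * pi * 7 * t), fs), 5, 10)
  dph <- (pc$phase - ps$phase)[core]
  dph <- atan2(sin(dph), cos(dph))
  expect_true(all(abs(dph - pi / 2) < 0.02))
  # chirp crossing the band: phase defined and bounded everywhere
  ch <- narrowband_phase(lfp_signal(sin(2 * pi * (2 * t + 0.3 * t^2)), fs), 5, 10)
  expect_true(all(is.finite(ch$phase)))
  expect_true(all(abs(ch$phase) <= pi + 1e-12))
  expect_error(narrowband_phase(lfp_signal(rnorm(4000), fs), 100, 105), "unsupported-band")
  expect_error(narrowband_phase(lfp_signal(rnorm(4000), fs), 5, 12), "granularity")
})

test_that("PLV formula is exact on constructed phase series", {
  th <- runif(500, -pi, pi)
  expect_equal(plv(th, th), 1.0)
  expect_equal(plv(c(0, pi / 2, pi, 3 * pi / 2), rep(0, 4)), 0, tolerance = 1e-12)
  expect_error(plv(th, th[-1]), "lengths differ")
  # symmetry and common-offset invariance
  th2 <- runif(500, -pi, pi)
  expect_equal(plv(th, th2), plv(th2, th))
  expect_equal(plv(th + 0.7, th2 + 0.7), plv(th, th2), tolerance = 1e-12)
  expect_gte(plv(th, th2), 0)
  expect_lte(plv(th, th2), 1)
})

test_that("uniform-phase null PLV scales as the random-walk modulus", {
  # oracle: E|mean of N unit phasors| = sqrt(pi)/2 * N^(-1/2)
  set.seed(12)
  n <- 1e4
  vals <- replicate(50, plv(runif(n, -pi, pi), numeric(n)))
  expect_lt(mean(vals) / (sqrt(pi) / 2 / sqrt(n)), 3)
  expect_gt(mean(vals) / (sqrt(pi) / 2 / sqrt(n)), 1 / 3)
})

test_that("band PLV averages sub-bands and separates coupled from uncoupled bands", {
  fs <- 2000
  cfg <- gen_config(fs = fs, duration_s = 30, seed = 6)
  bg <- gen_background(cfg)
  expect_equal(band_plv(bg, bg, "theta"), 1.0)
  # independent channels stay near the narrowband null floor
  bg2 <- gen_background(gen_config(fs = fs, duration_s = 30, seed = 60))
  expect_lt(band_plv(bg, bg2, "theta"), 0.15)
  pr <- gen_coupled_pair(gen_config(fs = fs, duration_s = 60, seed = 19), coupling_spec(kappa = 2))
  expect_lt(abs(band_plv(pr$sig1, pr$sig2, "theta") - plv_expected(2)), 0.05)
  expect_lt(band_plv(pr$sig1, pr$sig2, "beta"), 0.2)
})

test_that("estimated PLV is monotone in the coupling concentration", {
  est <- vapply(c(0.5, 1, 2, 4), function(k) {
    pr <- gen_coupled_pair(gen_config(duration_s = 30, seed = 77), coupling_spec(kappa = k))
    band_plv(pr$sig1, pr$sig2, "theta")
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("session sync vectors are complete, bounded, and fail on missing channels", {
  rec <- shared_signal_recording(duration_s = 10, seed = 2)
  sv <- session_sync_vector(rec)
  expect_equal(nrow(sv), 32)
  expect_true(all(abs(sv$plv - 1) < 1e-9))
  expect_equal(sort(unique(sv$band)), sort(canonical_bands()$name))
  expect_equal(length(unique(sv$pair)), 8)
  v <- sync_vector_values(sv)
  expect_equal(length(v), 32)
  rec2 <- rec
  rec2$signals$RmPFC <- NULL
  expect_error(session_sync_vector(rec2), "incomplete-montage.*RmPFC")
})

test_that("a theta-coupled pair surfaces in exactly its sync-vector entry", {
  cfg <- gen_config(duration_s = 30, seed = 23)
  ses <- gen_session(cfg, couplings = list("LHC-RHC" = coupling_spec(kappa = 4)))
  sv <- session_sync_vector(ses$rec)
  hit <- sv$plv[sv$pair == "LHC-RHC" & sv$band == "theta"]
  expect_lt(abs(hit - plv_expected(4)), 0.07)
  others <- sv$plv[!(sv$pair == "LHC-RHC" & sv$band %in% c("theta"))]
  expect_true(all(others < 0.35))
})
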