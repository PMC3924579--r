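# small fixtures shared across test files; everything is generated in code

sinusoid <- function(freq, duration_s = 10, fs = 2000, amp = 1, phase = 0) {
  t <- seq_len(round(duration_s * fs)) / fs
  lfp_signal(amp * cos(2 * pi * freq * t + phase), fs)
}

# recording in which every montage channel carries the same series
shared_signal_recording <- function(duration_s = 10, seed = 1) {
  cfg <- gen_config(duration_s = duration_s, seed = seed)
  bg <- gen_background(cfg)
  mt <- canonical_montage()
  sigs <- lapply(mt$channels, function(ch) lfp_signal(bg$x, cfg$fs, ch))
  names(sigs) <- mt$channels
  recording(sigs)
}

# hand-built variance profile carrying a boxcar above an obvious floor
boxcar_profile <- function(lo_s, hi_s, fs = 1000, total_s = 10, base = 1, high = 100) {
  v <- rep(base, total_s * fs)
  v[(lo_s * fs + 1):(hi_s * fs)] <- high
  structure(list(v = v, fs = fs, n_src = total_s * fs, decim = 1L),
            class = "variance_profile")
}

# analytic circular path: r fixed, angle from a0 over n_loops full turns
circle_path <- function(n_loops = 3, r = 30, a0 = pi, duration_s = 300, n = 3000) {
  th <- seq(a0, a0 + n_loops * 2 * pi, length.out = n)
  data.frame(t_s = seq(0, duration_s, length.out = n),
             x_cm = r * cos(th), y_cm = r * sin(th))
}
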