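Package: neurosync
Title: Spike-Wave Detection and Phase-Synchrony Analysis for Rodent Field Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-channel rodent local field potential
    (LFP) and epidural EEG recordings: Welch power spectra with line-noise
    interpolation, band-limited phase-locking values (PLV) between electrode
    pairs assembled into 32-dimensional session synchrony vectors, automatic
    detection of spike-wave discharges by a Morlet wavelet sliding-variance
    classifier, per-cycle spike-wave morphology features with group
    distribution comparisons, PCA-based multidimensional synchrony-pattern
    distance analysis, and active place avoidance scoring from arena
    trajectories.  Includes a seeded synthetic-data generator (1/f background,
    von Mises coupled oscillator pairs with closed-form expected PLV,
    parameterized spike-wave trains, group-structured synchrony vectors,
    rotating-arena trajectories) that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
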