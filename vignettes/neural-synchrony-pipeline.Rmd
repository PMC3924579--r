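---
title: "Detecting spike-wave activity and quantifying band-limited synchrony in rodent field potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting spike-wave activity and quantifying band-limited synchrony in rodent field potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurosync)
```

## What this package computes

`neurosync` analyses multi-channel rodent local field potential (LFP) and
epidural EEG sessions recorded during behaviour on an 8-site montage:
left/right dorsal hippocampus, left/right medial prefrontal cortex (mPFC),
and four epidural screws.  Four analyses are chained together:

1. **Power spectra.** Each channel is normalized by its RMS (removing
   electrode-specific gain), cut into 5-s non-overlapping windows, and
   Welch-averaged.  The 58-62 Hz region is replaced by linear interpolation
   to remove mains contamination, and the PSD is normalized to unit total
   power so sessions and animals are comparable.
2. **Phase-locking values (PLV).** For each of the 8 canonical electrode
   pairs and each frequency band (theta 5-15, beta 20-30, slow gamma 30-55,
   fast gamma 65-100 Hz), the band is tiled into 5-Hz sub-bands; each
   sub-band signal is zero-phase FIR filtered, its instantaneous phase taken
   from the analytic signal, and

   $$\mathrm{PLV} = \frac{1}{N}\Bigl|\sum_{n=1}^{N} e^{i\,\theta_n}\Bigr|,
   \qquad \theta_n = \phi_1(n) - \phi_2(n),$$

   is evaluated over the whole trial and averaged across the sub-bands.
   The 8 pairs x 4 bands give a 32-dimensional synchrony vector per session.
3. **Spike-wave discharge (SWD) detection.** A Morlet continuous wavelet
   transform (scales 5-50, step 5, pseudo-frequencies ~16-160 Hz at the
   1000-Hz working rate) feeds a per-scale 50-ms sliding variance, summed
   over scales and smoothed (50 ms).  Candidates are threshold crossings of
   this profile; gaps < 0.75 s are filled; segments < 1 s are dropped; a
   segment is kept only if at least 50% of the inter-spike intervals between
   its variance maxima correspond to 2-10 Hz.  Prevalence is detected time
   over analyzed time.  Morphology features (spike duration, spike-to-valley
   voltage, inter-spike time, wave duration, wave energy) are extracted per
   cycle on 100-Hz low-passed marked segments.
4. **Pattern and behaviour analysis.** PCA of the 32-D vectors, projection
   onto the first six components, within/between-group mean pairwise
   Euclidean distances with multiple-comparison-adjusted significance, and
   place-avoidance scoring (shock-zone entrances, average speed) correlated
   with synchrony.

No public recordings exist for the kind of experiment this pipeline targets,
so the package ships a synthetic-data generator whose outputs carry exact
ground truth; every stage is validated against that ground truth or against
an independent oracle (closed forms, brute-force enumeration, or independent
matrix decompositions).

## The synthetic-data generator

The generator is first-class, tested code, and its defaults define the
conditions under which the pipeline is validated.

**Background.** White Gaussian noise shaped in the frequency domain with
amplitude $\propto f^{-a/2}$ gives an exact $1/f^a$ power spectrum
(default exponent 1), rescaled to 50 uV RMS — typical magnitudes for rodent
LFP after 1-500 Hz band-pass at 2000 Hz.  Spectral shaping was chosen over
autoregressive approximations because it is exact and seedable.

**Coupled oscillator pairs.** Both channels share a frequency-modulated
carrier confined to the requested band; channel 2 is offset by a phase
difference $\delta(t)$.  $\delta(t)$ is built by sweeping the quantile
function of the von Mises$(\mu, \kappa)$ distribution: $u(t)$ advances
linearly around the unit circle (period 2.5 s) and
$\delta(t) = \mu + F^{-1}_{\kappa}(u(t))$.  Over whole sweeps the empirical
distribution of $\delta$ is *exactly* von Mises, so the population PLV is
the Bessel ratio $I_1(\kappa)/I_0(\kappa)$ with no Monte-Carlo error from
the phase draws.  An i.i.d. block construction was rejected: to push the
sampling error of the mean resultant below the validation tolerance it
would need on the order of a thousand independent blocks per minute, far
below the temporal resolution of a 5-Hz filter bank.  The default
oscillation amplitude is 400 uV against the 50 uV background — strong
task-related theta — chosen so that additive-noise phase jitter attenuates
the estimated PLV by well under the validation tolerance; at low in-band
SNR the PLV estimator is biased toward zero, which is a property of the
estimator (and of the real recordings), not of the generator.

**Spike-wave trains.** Each cycle is a closed-form morphology: a shallow
pre-spike notch (depth 15% of the wave amplitude), a raised-cosine spike of
configurable width and amplitude, and a negative half-cosine wave whose
trough (the "valley") sits at `-wave_amp` 30% of the way through the
inter-spike span.  The notch exists so that the two minima flanking a spike
have unequal voltages: the spike-duration feature is defined at the level of
the *higher* flanking minimum, and with symmetric waves that level would
touch the waveform only tangentially, making the width ill-posed.  Ground
truth records every spike time and the per-cycle feature values implied by
the closed form.

**Sessions, synchrony vectors, trajectories.** Full sessions superimpose
per-channel background, per-pair coupled oscillations, scheduled trains on
the screw channels (where such activity is most prominent in vivo), optional
60-Hz line and hard clipping at a configurable rail.  Synchrony-vector
fixtures are isotropic Gaussian clouds around given 32-D centroids clipped
to [0,1]; the default 40 vectors per group emulates five animals
contributing eight sessions each.  Trajectories emulate an overhead tracker
at 30 Hz on a 41-cm-radius rotating arena with random-walk or
zone-avoiding policies.

**What the generator does not emulate.** No biophysical dynamics: real SWDs
have variable cycle morphology and harmonics; real theta is asymmetric and
cross-frequency coupled; real backgrounds are non-stationary across
behavioural state.  Passing the validation suite therefore demonstrates the
*algorithmic* correctness of the pipeline under controlled statistics, not
field-readiness for any particular recording system.

## Numerical choices

* **FIR phase filters**: windowed-sinc (Hamming) of order `3 fs / lo`
  rounded to even and capped at a third of the signal length, applied
  forward-backward for zero phase.  One filter length at each edge is
  excluded from every PLV sum because the analytic signal and the
  forward-backward filter are unreliable there.
* **Sub-band tiling** is contiguous from each band's lower edge (theta
  5-10/10-15, beta 20-25/25-30, slow gamma five tiles, fast gamma seven);
  band edges are half-open so 30 Hz belongs to slow gamma only.
* **Welch details**: Hamming taper, per-window mean removal, trailing
  partial windows discarded, scaling such that a unit-RMS signal has unit
  total PSD power.
* **Detector threshold**: `median + 6 * MAD` of the variance profile over
  analyzed time.  Robust statistics tolerate the events themselves
  inflating the right tail; an absolute threshold would need per-animal
  calibration.  `tune_threshold_k()` sweeps the multiplier against
  synthetic ground truth for users who want to recalibrate.
* **Wavelet working rate**: 2000-Hz inputs are decimated to 1000 Hz inside
  the detector so that Morlet scales 50..5 map onto pseudo-frequencies
  ~16-160 Hz; at 2000 Hz that mapping is not satisfiable with standard
  Morlet parameters.
* **Local maxima** in the variance profile must clear a prominence of 5% of
  the threshold; raw sample-level maxima would fragment inter-spike
  intervals.  Extrema plateaus resolve to their centre sample.
* **Spike width bounds**: the amplitude rule (>= 400 uV above the higher
  flanking minimum) and minimum width (>= 50 ms) are applied as stated;
  a `width_max_ms` is exposed in `feature_params()` for users who prefer to
  bound sharp transients from above, and is disabled by default.
* **Wave energy** is the raw sum of squared amplitudes over the
  wave-duration samples (per-sample, not per-second); values therefore
  scale with the sampling rate, which is constant within a study.
* **Saturation**: runs at the rail shorter than 50 ms are tolerated (large
  spike components may clip); longer runs are excluded from analyzed time,
  and a channel is dropped when more than 5% (configurable) of its time is
  excluded — the threshold for "substantial" saturation is not standardized,
  so it is a config entry.

## Statistics on group distances

The mean pairwise 6-D distance within a group and against a reference group
summarizes how distinct treatment groups are in synchrony space.  Comparing
these distance sets with two-sample t-tests that treat each pair as an
independent observation is the field's stated procedure, and the t statistics
are reported verbatim.  But pair distances share underlying sessions: their
effective sample size is the number of sessions, not the number of pairs, and
simulation on identical groups (four groups of 40, 50 replicates) showed the
naive t flags false separations in ~3 of 4 studies.  The significance flags
in `group_distances()` therefore come from group-label permutation tests
(499 permutations, exact under exchangeability), Bonferroni-adjusted over all
emitted comparisons; with them, identical groups are flagged in fewer than
10% of replicates while clearly separated clusters are still detected.  Both
contrasts — cross-distances against the reference group's within-distances
and against the tested group's own — are computed and reported, since either
reading of the procedure is defensible.

## Behaviour scoring

Entrances are transitions into a 60-degree shock sector fixed in room
coordinates.  A 0.5-s debounce (configurable) requires the animal to be
continuously outside the sector before the next entrance can be scored;
without it, tracker jitter at the sector edge inflates counts.  Scoring uses
room-frame coordinates only; the arena-frame rotation column is carried for
completeness.

## Problem sizes used in validation

The test suite and the acceptance script validate at sizes chosen to make
every stochastic tolerance comfortable: 60-s coupled pairs for PLV recovery
(tolerance 0.05 against the Bessel ratio), 50 detector benchmark sessions of
300 s with 3-6 trains each (sensitivity >= 0.9 at Jaccard >= 0.5), a
27-point morphology grid (cycle rate 4-8 Hz, width 50-80 ms, amplitude
500-1200 uV; median feature error < 10%), and 50 replicate identical-group
studies for the type-I check.

## Known limitations

* PLV estimates are biased toward zero at low in-band SNR and biased away
  from zero for short recordings (the null floor scales as $N^{-1/2}$ in the
  number of effectively independent phase samples); compare only sessions of
  similar length and signal quality.
* The detector's scale set targets the broadband energy of sharp spikes; it
  will miss spike-wave variants whose spike component is slower than ~60 Hz
  content entirely.
* Feature extraction assumes the canonical spike-then-wave polarity
  (positive spike, negative wave); recordings with inverted polarity should
  be negated first.
* The permutation flags assume sessions are exchangeable across groups under
  the null; nested structure (sessions within animals) is not modelled.
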