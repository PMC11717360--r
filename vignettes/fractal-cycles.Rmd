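---
title: "Fractal cycles of sleep: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractal cycles of sleep: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fraccyc)
```

## The model

Sleep EEG spectra mix narrowband oscillations (delta, sigma, alpha, ...)
with a scale-free aperiodic background whose power decays as a power law,
`P(f) ∝ f^β`. The exponent — equivalently the slope of the spectrum in
log-log coordinates — indexes the balance of slow against fast activity: it
is steepest (most negative) in slow-wave sleep and flattest in REM sleep and
wake. Tracked epoch by epoch across a night, the slope rises and falls 4-6
times, and this package defines a *fractal cycle* as the interval between
two successive prominent peaks of the smoothed, z-normalized slope series:
a descent from a local maximum to a local minimum and the ascent back,
with both excursions exceeding 0.9 z. Because slope is a continuous,
automatically computed quantity, fractal cycles provide an objective
counterpart to classical non-REM - REM cycles scored from hypnograms, and
they remain defined in situations where hypnogram rules are awkward —
most notably cycles whose expected REM episode is replaced by a brief
lightening of sleep ("skipped" cycles).

## Pipeline and tunable parameters

1. **Epoching and channel averaging** (`read_edf()`,
   `average_channels()`). The EEG is averaged over the analysis channels
   (typically F3 and F4) and cut into the scoring grid: 30 s epochs, or
   20 s where the staging used 20 s. Manually scored artifact epochs are
   excluded before any automatic analysis.
2. **IRASA** (`irasa()`). Resampling factors `hset = 1.1, 1.15, ..., 1.9`
   (the common default of the originating toolbox); for each `h` the
   geometric mean of the PSDs of the `h`- and `1/h`-resampled signal
   cancels oscillatory peaks, and the median across `h` is the fractal
   spectrum.
3. **Slope fit** (`fit_loglog_slope()`). OLS of `log10` power on `log10`
   frequency over 0.3-30 Hz. The 0.3-18 Hz band should be used for
   recordings low-pass filtered near 18-35 Hz, and 1-30 Hz is a useful
   sensitivity band when spectral "knees" below 1 Hz are a concern. At
   least 5 positive bins are required; nonpositive fractal bins (possible
   at spectral edges after the median) are dropped because their log is
   undefined.
4. **Detection** (`detect_fractal_cycles()`). z-normalization (sample sd),
   Savitzky-Golay smoothing of order 5 with a 101-epoch frame, then peak
   finding with minimum prominence 0.9 z and minimum distance 20 min
   (40 epochs of 30 s, 60 of 20 s). The frame is specified in epochs, not
   minutes, so a 20 s grid smooths a shorter real-time window — matching
   how the reference settings were transferred across datasets; pass a
   recomputed frame if a fixed-duration window is preferred. Sensitivity
   presets worth reporting alongside the defaults: frame 51/101/151,
   prominence 0.7/0.9/1.1.
5. **Classical cycles** (`segment_cycles()`, `split_skipped()`) and
   **matching/statistics** (`match_cycles()`, `spearman()`,
   `prevalence_map()`, `prevalence_hpdi()`, ...).

## Numerical choices

**PSD estimation.** Within an epoch the PSD is a Hann-tapered Welch
estimate. The default uses 10 s segments with 0.9 fractional overlap: the
segment averaging keeps single-bin periodogram noise low enough that the
geometric mean inside IRASA is nearly unbiased relative to the total
spectrum (with one full-length taper the geometric mean of two
exponentially distributed periodogram ordinates is biased low by ~20%,
which cancels in slope fits but distorts the oscillatory residual).
`compute_psd()` with its own defaults uses a single full-length taper,
whose grid is finer than 1/epoch-length Hz.

**Resampling.** IRASA resampling is done in the Fourier domain (truncate or
zero-pad the spectrum, i.e. ideal brick-wall anti-aliasing), with target
lengths rounded to the next 5-smooth integer so that every FFT length is
fast for R's mixed-radix FFT. The effective `h` therefore deviates from the
nominal value by under 1%; since the up/down factors enter as a reciprocal
pair, a small common deviation multiplies the fractal spectrum by a
constant and leaves the fitted slope unchanged.

**Peak semantics.** `find_peaks()` reproduces MATLAB `findpeaks`: strict
local maxima (a flat top reports its first sample; series endpoints are
never peaks), prominence measured against the higher of the two flanking
minima taken to the nearest higher sample or the border, prominence
filtering before the distance rule, and the distance rule applied tallest
first. Peaks exactly `min_distance` apart are kept; only strictly closer
peaks are discarded.

**Missing epochs.** Artifact and failed-fit epochs are removed and the
remaining series is treated as contiguous for smoothing and peak finding
(gap-aware smoothing is not attempted), but every output carries original
epoch indices, and durations are always computed on the original time base.
z-normalization uses all retained epochs between lights-off and lights-on,
including wake: the normalization is within-participant and wake epochs are
part of the recorded series; excluding them would shift the 0.9 z
prominence threshold in nights with much wakefulness.

**HPD intervals.** The prevalence posterior is Beta(k+1, n-k+1) on the
per-test success probability, truncated to `[α, 1]` and mapped through
`γ = (θ − α)/(1 − α)`. The highest-density interval is found by bisecting
on the density level, with the two crossings located by root search and the
enclosed mass evaluated exactly via the Beta CDF (tolerance 1e-8 mass) —
no grid approximation; the unit tests check it against a 10^6-point grid
oracle.

**Classical-rule operationalizations.** Three details the rule set leaves
open are fixed as follows, each exposed as a parameter. (i) A REM episode
tolerates interruptions shorter than 15 min before it is considered
terminated. (ii) The ≥20 min of N2/SWS required before a terminating REM
episode is cumulative within the cycle, not necessarily contiguous; a REM
episode arriving earlier (e.g. sleep-onset REM) is absorbed into the
ongoing cycle. (iii) A "lightening of sleep" that splits a long (>110 min)
cycle is a continuous run of wake/N1/N2/movement of at least 12 min that is
flanked by slow-wave sleep, or failing that one that begins in the middle
third of the cycle; the split point is the first epoch of the run, at most
one split is made per cycle, and a split is rejected if either half would
be shorter than 12 min. Movement time is treated as wake inside these
rules. The cycle-matching criterion (overlap of at least half the shorter
cycle, assigned greedily by overlap) is likewise a declared
operationalization of "approximately coinciding" cycle timing, not a rule
inherited from the hypnogram literature.

## The synthetic generator

`synth_hypnogram()` plants a stage schedule of N1 - N2 - SWS - N2 - REM
cycles with sampled durations (mean 90 min, sd 10, mid-night cycles
longest; SWS shrinking and REM growing across the night), optional short
WASO bouts, and an optional long skipped-REM first cycle built to satisfy
the splitting rule (>110 min, a 14-min lightening flanked by SWS blocks).
Sampled durations are truncated at 108 min so that an ordinary planted
cycle never crosses the 110-min split gate. `synth_eeg()` renders each
epoch as spectrally shaped colored noise with a stage-dependent exponent
(wake 1.0, N1 1.5, N2 2.2, SWS 3.0, REM 1.3 — generator conventions chosen
to reproduce the qualitative ordering wake/REM flattest, SWS steepest) plus
stage-gated sinusoids, crossfaded over half a second at epoch joins.
`synth_slope_series()` bypasses the EEG and plants the slope series
directly: cosine descent-ascent arcs between peaks at raw level −1.1 and
troughs near −3.0, a 30-min lead-in and tail so the edge peaks sit clear of
the Savitzky-Golay startup transient, and Gaussian epoch noise (sd 0.25).

What the generator does *not* emulate: spindle/K-complex morphology,
microarousals, stage-transition dynamics beyond the fixed template, and
realistic inter-subject variability. Passing the recovery tests therefore
shows that the detector and rules are internally consistent and robust to
epoch-level noise at realistic cycle geometry — not that they will match
human scoring on clinical data.

A known geometric effect of smoothing: a 101-epoch quintic filter applied
to arcs of unequal period shifts each peak by up to ~3 epochs toward the
broader arc, so even noise-free planted durations are recovered to within
about 3 min rather than exactly; the peak *finding* itself is exact, as the
unsmoothed-series tests show.

## Problem sizes in the test suite

The suite exercises the full pipeline at sizes chosen to keep it
comfortably reproducible on a laptop: slope-recovery checks use 50 epochs
of 30 s at 250 Hz per exponent, detector-oracle equivalence uses 1,000
random series of length 900, and planted-night recovery uses 20 seeded
nights of 4-6 cycles. These sizes are stated here so they can be scaled up
when stronger evidence is wanted.

## Limitations

* The detector does not distinguish wake-related from REM-related slope
  peaks; nights with abundant wake after sleep onset yield more, shorter
  fractal cycles than the hypnogram suggests. This is a property of the
  method, not a bug in the implementation.
* Smoothing-frame and prominence defaults were tuned (by the method's
  originators) on healthy adults; populations with shallower slope
  fluctuations (e.g. under REM-suppressive medication) may sit near the
  0.9 z threshold, which is why the sensitivity presets exist.
* EDF support covers continuous single-rate EEG channels; discontinuous
  EDF+D files and annotation channels are out of scope.
* No gap-aware smoothing: long artifact runs shorten the effective series
  that the 101-epoch frame sees.
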