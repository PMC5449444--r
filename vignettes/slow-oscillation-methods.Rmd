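---
title: "Detecting cortical Up/Down states and slow-oscillation metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cortical Up/Down states and slow-oscillation metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Under deep anesthesia (and in slow-wave sleep) the cerebral cortex
settles into a slow oscillation (SO, at or below 1 Hz): periods of
sustained network firing (Up states) alternate with near-silent periods
(Down states). The statistics of this alternation — its frequency, the
durations of the two states, the regularity of the cycle, the firing
rate sustained in each state, how Up-state onsets travel across the
cortical surface, and the fast (beta–gamma) rhythms nested inside Up
states — are a compact fingerprint of cortical network function, and
changes in them track aging and neurodegeneration-like phenotypes in
mouse models.

`slowosc` implements this analysis chain for extracellular local field
potential (LFP) recordings, together with a synthetic LFP generator with
exact ground truth, so that every stage can be validated quantitatively
without animal data.

## Up/Down detection from three fingerprints

Up states express themselves in three nearly disjoint frequency bands of
the same electrode signal:

1. **SO envelope** — the slow LFP deflection itself. The trace is
   averaged onto a 5 ms grid and low-pass filtered (default cutoff 2 Hz,
   zero-phase). In deep layers the Up deflection is negative; the
   envelope is sign-oriented so that Up comes out positive, using the
   correlation between the slow component and high-frequency signal
   power (falling back to the deep-layer sign convention when that
   correlation is negligible). Detection is therefore agnostic to
   recording polarity.
2. **Gamma variance envelope** — the variance of the gamma-filtered LFP
   (default band 20–80 Hz), computed in 5 ms bins and smoothed over
   50 ms. Up states ride on elevated gamma power.
3. **logMUA** — the mean periodogram power at 200–1500 Hz in
   non-overlapping 5 ms windows (rectangular taper), floored at
   10^-12 times the median power and natural-log scaled. Power in this
   band is proportional to the local population firing rate, so logMUA
   is a firing-rate proxy that needs no spike sorting.

The three series are z-scored and combined into a single detection
series by projection onto the first principal component, oriented to
correlate positively with logMUA. Because the features live in three
separate bands, a narrow-band artifact can corrupt at most one of them,
and its PCA weight shrinks accordingly. A feature with zero variance is
dropped (weight 0) with a warning.

Choices the method leaves open, resolved here as package defaults: the
features are z-scored before PCA (so the combination is scale-free
across gain differences), only the first component is used, and the PCA
is computed per recording channel rather than pooled across recordings.
All bands and cutoffs are arguments.

### Thresholding and cleaning

The combined series is bimodal when states alternate. The threshold is
placed at the deepest density valley between the two dominant modes of
its distribution. When the density is unimodal the boundary of a 1-D
2-means split is used instead — but only if the split is credible: we
require a mean silhouette of at least 0.2 **and** a Sarle bimodality
coefficient above 5/9 (the uniform/normal reference value). The second
gate matters because splitting any unimodal Gaussian with 2-means
produces two half-normals about 1.6 SD apart and a silhouette near 0.5,
so a silhouette test alone would happily "segment" pure noise. With both
gates, a stationary signal raises `no state alternation detected`.

The binary series is then cleaned: gaps shorter than `merge_gap_s`
(default 0.05 s) between Up runs are merged, runs shorter than
`min_state_s` (default 0.1 s) are absorbed into their flanking state
(shortest first), and partial states at the recording edges are dropped.
A cycle is a Down state followed by the Up state that terminates it, so
cycle tables anchor on the Down-to-Up transition.

### SO metrics

Per cycle, frequency is the inverse of the whole Up+Down duration. The
SO frequency of a recording is the **mean of per-cycle frequencies**
(not the inverse of the mean period; the two differ under cycle
variability), the cycle-variability index `cv_freq` is the sample SD of
per-cycle frequency over its mean, and state durations are arithmetic
means.

## Firing-rate metrics

`fr_up` / `fr_down` are the mean logMUA over bins falling (by bin
centre) inside Up / Down intervals. The relative firing rate `rel_fr`
averages the logMUA waveform in a ±0.5 s window around every Down-to-Up
transition, subtracts the pre-transition (Down) mean, and takes the
maximum of the post-transition portion — averaging strictly precedes the
maximum, which matters whenever transition peaks are asynchronous.

## Traveling waves

On a linear array (16 contacts, 100 µm apart by default), Up-state
onsets are grouped into waves by a recursive window algorithm: the
initial window is half the pooled median inter-onset interval; onsets
join a wave if they fall within the window of its provisional mean time,
one per channel; the window shrinks by 0.75 per iteration until the
assignment is stable or the window reaches 20 ms. Partial waves with
disjoint channel masks and compatible times are then merged, and waves
with fewer than 10 participating channels are rejected. Lags are
relative to the wave's mean onset.

Lag vectors are clustered with k-means (k = 5, capped at the number of
waves and of distinct patterns; fixed seed, 50 restarts, so results are
reproducible; missing channels imputed by the running cluster mean).
Per cluster, speed = distance between the extreme-lag electrodes divided
by their lag difference; the recording-level speed is the cluster
average weighted by the proportion of waves. Degenerate clusters (zero
lag spread) are excluded with renormalized weights and a warning. Speed
is reported unsigned; the propagation direction is summarized separately
as the sign of the lag-versus-position slope.

## Spectra and power excess

Per-state spectra use Welch's method: Hann windows of 5000 samples with
50% overlap, drawn only from within same-state segments — segments
shorter than one window are skipped rather than concatenated, which
avoids stitching artifacts at state boundaries but means very short Up
states do not contribute. The window length is interpreted at the
recording's native rate (at 20 kHz, 250 ms and 4 Hz resolution; at the
10 kHz used in the bundled analyses, 2 Hz resolution) and is an
argument.

The aperiodic background is fitted as P(f) = A/f^α by log–log
regression over 5–100 Hz with two passes that exclude bins more than
2 SD above the fit, so narrow oscillatory peaks do not bias α. The free
exponent treats "1/f decay" as a family; a strict α = 1 fit is available
via the `alpha` argument. The **power excess** is the ratio PSD/fit; its
maximum within 10–90 Hz localizes the beta–gamma synchronization peak.
The excess is invariant to signal gain (numerator and denominator both
scale by the squared gain), and an excess curve flat to within 0.1%
relative range is flagged rather than assigned a spurious peak.

## Sample entropy

SampEn(m, r, N) is −ln of the conditional probability that sequences
similar for m points (Chebyshev distance ≤ r) remain similar at m+1,
self-matches excluded, with both template lengths drawn from the first
N−m starting points (the Richman–Moorman convention). Defaults m = 2,
r = 0.25. The tolerance r is interpreted as 0.25 × the SD of each
individual state segment's logMUA bins (the convention of the SampEn
literature; an absolute-r mode exists), which makes the metric invariant
to affine transforms of the series. SampEn is computed within every
single Up and Down state and averaged over homologous states; segments
shorter than 10 bins (50 ms) are skipped and a constant segment counts
as SampEn 0 (perfect regularity). Undefined values (no matching
template pairs) are excluded from the averages, with usable-state counts
reported.

## Group statistics

Group contrasts use the classic pooled-variance Student t-test for
independent samples (Welch available via a flag), Pearson correlation
with the t-transform p-value, and mean ± SE summaries. Pooled-area
comparisons enter every per-recording area value as one observation. No
multiple-testing correction is applied; p-values are reported raw with a
note.

## The synthetic generator

The generator emulates exactly the statistical structure the detector
relies on: alternating states with controllable duration statistics, a
negative Up-state slow deflection (20 ms raised-cosine ramps), an
Up-state gamma oscillation with per-state random phase, a Poisson
unit-event train (1 ms biphasic kernel, gamma-distributed amplitudes)
whose rate switches between `up_rate_hz` and `down_rate_hz`, and a 1/f
background (power exponent 1) made by spectral shaping of white noise.
Defaults: up 1500 events/s vs down 150 events/s (Down deliberately not
silent, so Down-state firing metrics stay well defined), gamma 40 Hz at
amplitude 0.3, slow deflection 1, event kernel 0.5, background 0.3 —
amplitudes are arbitrary units by design, since LFP calibration is not
modeled. Samples are float32-quantized at synthesis (the acquisition
convention), which makes file round-trips bit-exact.

**Durations.** Up and Down durations are independent gamma variates
with the requested means and a common shape k. Because the headline
regularity statistic is the CV of per-cycle *frequency* 1/(U+D), k is
tuned numerically — inverse moments of U+D computed by the
Laplace-transform identity and a root search — so that CV(1/T) equals
`cycle_cv` exactly in expectation. `cycle_cv = 0` degenerates to
constant durations.

**Presets.** The four group × age cells are parameterized from the
study's printed pooled means (frequencies 1.02/0.72 Hz at 5 months and
0.91/0.77 Hz at 7 months; durations Down 0.71/1.1 s and Up 0.49/0.61 s
at 5 months; CVs 0.40/0.53 and 0.48/0.61). Printed pooled frequencies
and durations cannot both be matched by one parameter set, because the
mean per-cycle frequency exceeds the inverse mean period under cycle
variability (Jensen's inequality) and the printed values pool areas.
Hence two variants: `duration_matched` pins the mean durations to the
printed values, while `frequency_matched` scales the period distribution
so that E[1/T] equals the printed frequency while keeping the printed
Up:Down ratio. At 7 months only frequencies are printed, so 7-month
duration-matched parameters derive from the frequency with the group's
5-month Up:Down ratio.

**Arrays.** All channels share one cycle skeleton; channel c's Up
intervals are shifted by position_c/speed plus Gaussian jitter
(default SD 2 ms), with noise, gamma phases and unit events independent
per channel. The ground truth stores the exact per-wave lags.

### What the generator does not emulate

Electrode drift and movement artifacts, non-stationary anesthesia
depth, multi-area heterogeneity beyond preset parameters, realistic
spike waveform diversity, volume-conduction correlations between
channels beyond the shared state skeleton, and absolute amplitude
calibration. Passing the recovery suites therefore demonstrates that
the analysis chain is correct and unbiased under the assumed model, not
that it is robust to every pathology of real recordings.

## Numerical choices

* All filtering is zero-phase in the frequency domain (FFT masks with
  raised-cosine transitions). The 2 Hz corner at a 10–20 kHz sampling
  rate corresponds to a normalized frequency near 10^-4, where IIR
  designs are numerically fragile; a whole-trace FFT mask is exact and
  stable at any corner. FFT lengths are padded to composite sizes
  (edge-reflection padding) because R's mixed-radix FFT degenerates to
  quadratic time at prime lengths.
* The Welch PSD is one-sided and density-scaled; its integral matches
  the signal variance (Parseval) to within 1% on white noise, which the
  tests assert.
* Bins are assigned to states by bin centre; intervals are half-open
  `[start, end)`; sample indices are 0-based and all times are seconds.
* k-means steps use fixed seeds (and 50 restarts for lag clustering), so
  reruns are bit-identical.

## Problem sizes and accuracy

The bundled analyses and recovery suites run at 10 kHz — the full
acquisition rate of 20 kHz carries no extra information for any metric
here (the highest band ends at 1500 Hz) and doubles cost. Recovery runs
use 300 s per recording (roughly 200–300 cycles) for duration/CV/
frequency estimates, 120 s of 16-channel data (~90 waves) for speed,
and 60 s for label agreement and spectral peaks.

Known small biases, visible in the recovery tables: absorbing states
shorter than 0.1 s merges occasional fast cycles into slow ones, which
depresses detected SO frequency by roughly 2–4% and the frequency CV by
up to ~0.05 for the high-CV presets; both remain comfortably inside the
10%/±0.07 recovery bands and disappear as `cycle_cv` decreases. The
CV of per-cycle frequency is also intrinsically noisy: with ~200 cycles
its sampling SE is about 0.03.

## Limitations

The detector assumes one dominant bimodal alternation per channel; it
does not stage sleep, reject artifacts, or sort spikes. Wave analysis
assumes a linear array geometry and onset-based (not phase-based)
propagation. The spectral block needs state segments of at least one
Welch window, so extremely fragmented Up states yield no Up-state
spectrum. Group statistics treat pooled-area values as independent
observations, following the analysis convention they mirror.
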