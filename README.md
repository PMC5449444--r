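# slowosc

Analysis of cortical **slow oscillations** (SO) in extracellular local
field potential (LFP) recordings: detection of Up and Down states,
slow-oscillation metrics, population firing-rate estimation from
multi-unit activity, traveling-wave propagation speed, per-state power
spectra with 1/f power-excess peaks, and per-state sample entropy —
plus a synthetic multichannel LFP generator with exact ground truth so
the whole chain is testable without animal recordings.

It is written for electrophysiologists characterizing cortical network
dynamics under anesthesia or slow-wave sleep (e.g. comparing mouse
strains or disease models across ages), and for anyone who needs a
validated, scriptable Up/Down segmentation.

## The method

Up states leave three fingerprints in different bands of the same
electrode signal, which are combined into one detection series:

1. the **SO envelope** — LFP low-passed at 2 Hz (zero-phase), oriented
   so the Up deflection is positive;
2. the **gamma variance envelope** — variance of the 20–80 Hz-filtered
   LFP in 5 ms bins, smoothed over 50 ms;
3. **logMUA** — log of the mean periodogram power at 200–1500 Hz in
   5 ms windows, a population firing-rate proxy.

The three series are z-scored and projected on their first principal
component (PCA weighting); the combined series is thresholded at the
trough between its two distribution modes, and cleaned (gap merging,
minimum state duration, edge states dropped). From the resulting cycles
(a Down plus its terminating Up):

* SO frequency `f = mean(1 / (T_up,i + T_down,i))` and its
  cycle-variability index `CV = sd(f_i) / mean(f_i)`;
* state durations; absolute firing rates `fr_up`, `fr_down` (mean
  logMUA over homologous periods) and the relative firing rate (peak of
  the Down-baseline-zeroed average logMUA waveform after the
  Down-to-Up transition);
* per-state **sample entropy** SampEn(m = 2, r = 0.25 × segment SD) of
  the logMUA series;
* per-state **Welch spectra** (5000-sample Hann windows, 50% overlap,
  windows only within same-state segments), an aperiodic fit
  `P(f) = A / f^alpha`, and the **power excess** `PSD / fit` whose
  10–90 Hz maximum localizes the beta–gamma peak;
* on 16-channel linear arrays, Up-state onsets are grouped into
  **traveling waves** (recursive window algorithm, waves on < 10
  channels rejected), lag patterns clustered by k-means (k = 5), and the
  propagation speed estimated per cluster from the extreme-lag
  electrodes and averaged with wave-proportion weights.

Details, defaults and the design rationale are in
`vignettes/slow-oscillation-methods.Rmd`.

## Worked example

Simulate five minutes of a single channel with the SAMP8 5-month preset
(mean Down 1.1 s, mean Up 0.61 s, cycle-frequency CV 0.53) and analyze
it:

```r
library(slowosc)

p   <- preset("SAMP8_5M", "duration_matched", rate = 10000, seed = 1)
sim <- synthesize_channel(p, 300)
ana <- analyze_recording(sim$rec)
round(ana$metrics, 4)
#>  so_frequency   up_duration down_duration       cv_freq         fr_up
#>        0.7302        0.5897        1.1111        0.5359       -0.3109
#>       fr_down        rel_fr     sampen_up   sampen_down       peak_hz
#>       -2.1803        1.9074        1.9279        1.9041       40.0000
#>   peak_excess      alpha_1f
#>       80.5531        0.9919

label_agreement(ana$seg, sim$truth$up, 10000)
#> [1] 0.9917
```

The detected Down duration (1.111 s) and Up duration (0.590 s) recover
the preset means within a few percent, the cycle CV (0.536) matches the
target 0.53, the Up-state firing proxy sits ~1.9 log units above the
Down-state baseline, the Up-state excess-power peak lands exactly on the
generator's 40 Hz gamma, the aperiodic exponent is ~1 (the generator's
1/f background), and detection agrees with the ground-truth labels on
99% of 5 ms bins.

## Analysis workflow

The `analysis/` scripts run the full study-style workflow on synthetic
cohorts and write their tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | simulate 4 recordings per group × age cell from the presets; save payload+sidecar files and a manifest |
| `02_detect.R` | detection + SO/firing/entropy metrics per recording → `metrics.csv`, per-cycle tables |
| `03_waves.R` | 16-channel array simulation, wave grouping, lag clustering, weighted speed → `waves.csv` |
| `04_spectra.R` | per-state Welch spectra, 1/f fits, excess-peak summary → `spectra/`, `spectra_summary.csv` |
| `05_group_stats.R` | group mean ± SE summaries and Student t contrasts → `summary.csv`, `tests.csv` |

Run them in order from the repository root with `Rscript`.

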