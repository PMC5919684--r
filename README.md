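# vocamps

Amplitude modulation power spectra of vocalization sequences: why the
temporal envelope of vocal communication sounds — rodent pup calls,
birdsong, monkey calls, infant cries, running speech — shows a
scale-invariant **1/f² modulation spectrum**, and how to measure, model and
predict it.

The package is aimed at bioacousticians and auditory neuroscientists who
want to (i) extract and characterize the amplitude modulation power
spectrum (AMPS) of a recording, (ii) decompose a vocalization sequence into
a rectangular-pulse envelope model, and (iii) test the shot-noise theory
that links the pulse statistics to the dual-regime lowpass shape of the
AMPS.

## The model

A vocalization sequence envelope is approximated as a train of `N ≅ λT`
non-overlapping rectangular pulses,

```
x(t) = Σₙ Aₙ · rect((t − tₙ)/Dₙ)
```

with random onset times `tₙ`, durations `Dₙ` and peak amplitudes `Aₙ`.
When the parameters are independent and onsets serially uncorrelated, the
modulation power spectrum is

```
S(f) = λ · E[A²] · E[sin²(πDf)] / (π²f²)
```

— flat below a cutoff and falling as `1/f²` above it (exponent α = 2).
For durations uniform on `[T₁, T₂]` the expectation is closed-form, the
zero-frequency plateau is `λE[A²](T₂² + T₁T₂ + T₁²)/3`, and the half-power
cutoff is approximately

```
f_c ≈ (1/π) / sqrt(μ_D² + σ_D²) = (1/π) / sqrt(E[D²])
```

so longer vocalizations put the 1/f² regime at lower modulation
frequencies: a time–frequency tradeoff carried entirely by the duration
statistics. Amplitude and rate only scale the spectrum; the **temporal
edges** (onsets/offsets) of variable-duration vocalizations create the
scale invariance, through ensemble averaging of sinc² pulse spectra.

## What the package provides

* **Envelope extraction** — Kaiser FIR bandpass (β = 5.6, order 640) to the
  species' vocal band, Hilbert-transform analytic envelope, a 250 Hz
  anti-aliased, decimated, unit-SD analysis envelope and a 30 Hz
  B-spline-smoothed segmentation envelope (`bandpass()`,
  `analytic_envelope()`, `lowpass_decimate()`, `extract_envelopes()`).
* **Segmentation** — noise-referenced threshold detection of isolated
  vocalizations (`estimate_noise()`, `detect_segments()`).
* **Pulse fitting** — per-segment least-squares rectangular pulse fits and
  assembly into a pulse sequence (`fit_pulse()`, `fit_pulses()`,
  `assemble_sequence()`, `render_model_envelope()`).
* **Spectra** — multitaper (Slepian/DPSS) AMPS estimation, first-order
  lowpass cutoff fits, power-law exponent fits, dB comparison, constant-Q
  modulation filterbank (`multitaper_amps()`, `fit_lowpass()`,
  `fit_scaling_exponent()`, `rms_db_error()`, `filterbank_amps()`).
* **Theory** — the closed-form model AMPS, its limits, and approximate and
  numeric half-power cutoffs (`closed_form_amps()`, `amps_low_limit()`,
  `amps_high_asymptote()`, `cutoff_approx()`, `cutoff_numeric()`).
* **Simulation & perturbations** — the stochastic pulse-train simulator and
  the constant-amplitude / constant-interval / zero-duration /
  duration-swap experiments (`simulate_envelope()`, `perturb()`,
  `perturbation_experiment()`).
* **Statistics** — joint Pearson correlations of fitted parameters with
  bootstrap errors, serial and point-process autocorrelations, interval
  histograms (`joint_correlations()`, `serial_autocorr()`,
  `point_process_autocorr()`, `interval_histogram()`).
* **Synthetic scenes** — pulse-modulated band-limited carriers over a noise
  floor, with per-species presets, so the whole pipeline is testable
  against known ground truth (`species_preset()`, `synth_scene()`,
  `render_scene()`, `write_scene()`, WAV/CSV/JSON I/O).

## Worked example

Generate two minutes of synthetic infant-cry audio from the built-in
preset (gamma durations with mean 0.33 s, rate 0.94 calls/s, 0.5–20 kHz
carrier, 30 dB SNR), then run the full pipeline:

```r
library(vocamps)

cfg <- pipeline_config(species = "infant", total_duration = 120, seed = 7)
report <- run_pipeline(cfg)
report
#> <vocalization pipeline report>
#>   vocalizations: 98 (rate 0.817 /s)
#>   mean duration: 0.354 s
#>   alpha (20-200 Hz): 1.38
#>   f_c: empirical 0.748 Hz, predicted 0.802 Hz
#>   data vs fitted-model AMPS: 0.78 dB rms (1-100 Hz)
```

Reading the numbers: 98 vocalizations were detected and fitted from the
audio; their mean fitted duration (0.354 s) recovers the generator's
duration statistics; the empirical half-power cutoff of the measured AMPS
(0.748 Hz) agrees with the cutoff predicted from the fitted duration
moments via `f_c ≈ (1/π)/sqrt(E[D²])` (0.802 Hz); and the AMPS of the
fitted rectangular-pulse model reproduces the AMPS of the actual envelope
to 0.78 dB RMS over 1–100 Hz. `glance(report)` returns the same summary as
a one-row tibble, and `autoplot(report$data_amps, lowpass = report$lowpass)`
draws the log-log spectrum with the fitted dual-regime lowpass.

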