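---
title: "Methods: modulation spectra of vocalization sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modulation spectra of vocalization sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the model it
implements, the estimator settings and why they are what they are, what
the synthetic-data generator does and does not emulate, and the design
choices made where more than one reasonable implementation existed. No
empirical number is claimed here beyond what the test suite and
`scripts/acceptance.R` compute.

## The stochastic pulse-train model

The temporal envelope of a vocalization sequence is modeled as a train of
non-overlapping rectangular pulses,
$$x(t) = \sum_{n=1}^{N} A_n\,\mathrm{rect}\!\left(\frac{t-t_n}{D_n}\right),
\qquad N \simeq \lambda T,$$
with onset times $t_n$, durations $D_n$ and amplitudes $A_n$ treated as
random variables. Each pulse stands for one isolated vocalization; the
pulse edges are the temporal acoustic edges (onsets and offsets) of the
calls. Under independence of the parameters and serially uncorrelated
onsets, the cross terms of the power spectrum vanish off DC and the
amplitude modulation power spectrum (AMPS) is the rate-weighted ensemble
average of single-pulse spectra,
$$S_{xx}(f) = \lambda\,E[A^2]\,
  \frac{E[\sin^2(\pi D f)]}{\pi^2 f^2},$$
a *dual-regime lowpass*: flat at low modulation frequencies, falling as
$1/f^2$ (scaling exponent $\alpha = 2$) above a cutoff. A single pulse has
a $\mathrm{sinc}^2$ spectrum with notches at multiples of $1/D$; averaging
across variable durations cancels notches and side-lobes into the smooth
$1/f^2$ trend while the main lobes add constructively into the flat
region. With durations uniform on $[T_1, T_2]$ the expectation is closed
form (`closed_form_amps()`), the plateau is
$\lambda E[A^2](T_2^2+T_1T_2+T_1^2)/3$ (`amps_low_limit()`), and the
half-power cutoff is approximately
$$f_c \approx \frac{1}{\pi\sqrt{\mu_D^2+\sigma_D^2}}
  = \frac{1}{\pi\sqrt{E[D^2]}}$$
(`cutoff_approx()`), with `cutoff_numeric()` solving
$S(f_c) = S(0)/2$ exactly by bisection as the oracle.

Two conventions worth stating explicitly:

* **sinc convention.** All closed forms use $\mathrm{sinc}(x)=\sin(x)/x$.
  With that convention the two printed forms of the uniform-duration
  solution (difference-of-sines and $T\,\mathrm{sinc}(2\pi T f)$) are
  algebraically identical, and the single-pulse spectrum
  $A^2D^2\mathrm{sinc}^2(\pi D f) = A^2\sin^2(\pi D f)/(\pi^2f^2)$ is
  consistent with them.
* **One- vs two-sided densities.** The closed form is a two-sided density
  (its integral over the whole line is Campbell's variance
  $\lambda E[A^2 D]$). The multitaper estimate is returned one-sided, as
  is standard. `theory_overlay()` doubles the closed form for $f>0$ so the
  two can be compared directly; all model–data RMS errors in the package
  use that alignment.

### Accuracy of the cutoff approximation

The $f_c$ approximation drops a bracketed sine term whose magnitude at the
crossing is bounded by $b = 1/(2\pi f_c (T_2-T_1))$, so its relative error
is bounded by $\sqrt{1+b}-1$. The often-quoted validity condition
$f_c > 1/(2\pi(T_2-T_1))$ only guarantees $b<1$, i.e. errors up to
$\approx 15\%$ for uniform supports with $T_1$ well above zero. The error
is monotone in the margin and reaches the 10% level when the support is
wide relative to its mean ($T_1 \approx 0$, where the margin takes its
maximal value $2\sqrt{3}$). The theory tests assert the derivable bound
and the monotone improvement; the acceptance check uses the
maximal-margin support.

### Validity regime of the closed form

The independence-based derivation neglects the interaction created by
enforcing non-overlap. At duty cycles $\lambda\mu_D \lesssim 0.15$ the
simulated multitaper AMPS agrees with the closed form to within 1 dB RMS
over 0.1–100 Hz; at duty cycles near 0.5 the refractory interaction
suppresses low-frequency power by several dB while the high-frequency
$1/f^2$ regime is unaffected. The oracle-equivalence tests therefore run
at $\lambda = 0.5$/s with uniform durations on $[0.05, 0.5]$ s (duty
$\approx 0.14$), while the scaling-exponent check runs at the stated
$\lambda = 2$/s, where only the $f > 20$ Hz regime is asserted.

## Envelope extraction

* **Bandpass**: Kaiser-windowed linear-phase FIR, $\beta = 5.6$, order
  640 ($\approx 60$ dB sidelobes), band set per species (30–100 kHz for
  rodent ultrasonic calls; 0.5–20 kHz otherwise, the 500 Hz floor leaving
  room to measure modulations up to 250 Hz). Filtering is forward-only
  with the group delay compensated by shifting, so onset times are
  unbiased for pulse fitting.
* **Envelope**: magnitude of the analytic signal, computed by the
  frequency-domain Hilbert construction on a 2-3-5-smooth padded length.
* **Analysis envelope**: 250 Hz Kaiser lowpass (transition to
  $1.5\times$ the cutoff, 60 dB), decimation by the per-species factor
  `DF`, scaling to unit standard deviation. Unit-SD scaling is applied
  *only* here, not to the segmentation envelope.
* **Segmentation envelope**: 5th-order B-spline lowpass — the five-fold
  convolution of a boxcar, smooth and continuously differentiable — with
  the boxcar width chosen so the composite $\mathrm{sinc}^5$ response has
  its $-3$ dB point at $f_m = 30$ Hz (the defining property; the width
  solves $\mathrm{sinc}(x_0) = 2^{-1/10}$, $\tau = x_0/\pi f_m \approx
  6.8$ ms). The realized $-3$ dB point is within a few tenths of a dB of
  30 Hz after rounding the width to samples.

## Segmentation

Vocalizations are detected in the 30 Hz envelope as maximal runs above
`noise_mean + T_x * noise_sd`, with the noise statistics measured in a
user-chosen noise-only window ($\approx 2.7$ s). `T_x = 30` for most
groups and 10 for rat and speech. Choices the procedure leaves open, and
what this implementation does:

* the threshold is referenced to the noise **mean** (not zero), which
  makes detection invariant to global amplitude scaling;
* each supra-threshold run is walked outward to the crossings of a
  secondary boundary level `noise_mean + 2 * noise_sd`, giving fuller
  pulse extents for fitting. The walk-out places segment edges roughly
  one smoothing-kernel half-width ($\sim 20$ ms) outside the true pulse
  edges; the pulse fitter recovers the exact edges from the 250 Hz
  envelope afterwards;
* runs closer than `min_gap = 20` ms are merged and runs shorter than
  `min_duration = 5` ms are dropped. 20 ms suppresses ripple-induced
  splits yet stays below vocal refractory gaps (tens to hundreds of ms),
  so genuinely distinct calls are not merged; a 50 ms window was measured
  to merge a substantial fraction of close call pairs at the infant
  preset's interval statistics and was rejected for that reason.

## Pulse fitting

One rectangular pulse is fitted per detected segment (joint optimization
of all $3N$ parameters does not converge at realistic $N$; per-segment
fitting is the tractable and standard alternative). Within the segment
padded by 100 ms, the fit minimizes the squared error on the 250 Hz
envelope. For a fixed support the optimal amplitude is closed form (the
envelope mean over the support — "peak amplitude" is read as fitted pulse
height), so the search is over (start, length) only: a coarse grid of at
most $\sim 160 \times 160$ candidates followed by exhaustive local
refinement at one-sample resolution. On SSE plateaus ties break toward
the smallest duration, then the earliest start — fixed and tested against
a brute-force oracle. Fitting is exact (zero SSE) on envelopes that are
themselves rectangular pulse trains. Overlapping fitted pulses are
truncated at the midpoint of their overlap (clamped when one pulse
engulfs the next).

## AMPS estimation

Multitaper PSD with Slepian (DPSS) tapers, $NW = 7/2$, $2NW-1 = 6$
tapers, transform length `nfft = 16384` (262144 for dense harmonic
structure such as the constant-interval perturbation). Long envelopes are
cut into non-overlapping `nfft`-sample blocks and tapered periodograms
averaged over blocks and tapers; shorter envelopes are zero-padded. The
envelope **mean is removed first**: the pulse train has a large mean whose
DC line would otherwise leak across the lowest bins and mask the flat
regime that the closed form (which drops the DC term) describes. Tapers
are computed in compiled code from the standard commuting tridiagonal
matrix via LAPACK's MRRR eigensolver, which remains accurate at
$N = 262144$ where the top eigenvalues cluster; the tests cross-check the
tapers against a dense sinc-kernel eigendecomposition at small $N$ and
assert spectral concentration at the large sizes.

Spectrum summaries are fitted on **log-spaced** frequency samples so the
flat and $1/f^2$ regimes carry comparable weight (linear sampling would
be dominated by high-frequency bins): the first-order lowpass model
$C/(f^2+f_c^2)$ in the dB domain (one-dimensional in $\log f_c$ after
profiling out $C$; dense grid over 0.01–1000 Hz plus local refinement,
with a flag when the optimum falls outside the fitted range, as for a
flat spectrum), the scaling exponent as an OLS slope of log power vs log
frequency, and RMS dB errors over 1–100 Hz by default.

## The synthetic-data generator

The generator emulates the *envelope statistics* the analysis depends on,
not species-accurate calls: a ground-truth pulse sequence is drawn from
the sequence model, rendered as a band-limited Gaussian-noise carrier
(tonal carrier optional) multiplied by the piecewise-constant pulse
envelope, optionally modulated by a vocal-fold-like periodic component
$1 + m\cos(2\pi f_0 t)$ ($f_0 \approx 190$ Hz for speech-like scenes),
plus a stationary white noise floor set by an SNR in dB. The carrier is
scaled by the Rayleigh envelope mean so a pulse of amplitude $A$ has
envelope $\approx A$. Presets carry the tabulated per-group recording
settings ($F_s$, band, `DF`, $T_x$) and sequence statistics (rate,
amplitude/duration/interval moments); durations and amplitudes use gamma
distributions matched by moments.

Non-overlap is enforced **by construction**: after each pulse a silent
gap equal to the refractory dead time plus an exponential draw, with the
exponential mean chosen so the onset-to-onset interval mean equals the
tabulated $\mu_I$ (hence the rate is exact). This preserves the duration
marginals exactly. A draw-then-redraw/truncate scheme was measured to
shorten realized durations by $\sim 20\%$ at the infant preset's duty
cycle (the redraw conditions durations on the gap), which would corrupt
the very statistics the pipeline is validated against. The cost is that
the realized interval *standard deviation* is
$\sqrt{\sigma_D^2 + (\mu_I-\mu_D-t_{dead})^2}$ rather than the tabulated
$\sigma_I$; the intervals keep their refractory-plus-exponential-tail
character. The dead time defaults to $\max(\mu_I-\sigma_I, 0)$.

What passing tests on these scenes do **not** show about real data: real
vocalizations have non-rectangular envelopes (attack/decay, vocal-fold
periodicity that the pulse model deliberately ignores), colored and
non-stationary background noise, parameter correlations, and possible
serial structure. The pipeline's recovery results on synthetic scenes
bound its behavior under the model's assumptions only.

## Perturbation experiments

`perturb()` implements four manipulations, each preserving exactly what
it claims: *constant amplitude* (single amplitude chosen analytically so
the rendered envelope variance is unchanged; onsets/durations bitwise
identical), *constant interval* (onsets on a strict 1 s grid; durations
capped at 0.9 interval; amplitudes kept — the AMPS becomes a harmonic
comb at 1 Hz whose peak amplitudes follow the $1/f^2$ envelope),
*zero duration* (durations zeroed; pulses render as single-sample
impulses of their original amplitudes, so the flat-AMPS level depends on
the envelope rate and only flatness, $|\alpha| < 0.2$, is asserted), and
*duration-distribution swap* (durations redrawn from a uniform,
exponential or gamma distribution with the empirical mean and variance;
matched-moment swaps leave the AMPS nearly unchanged, the model's
distribution-robustness property).

## Problem sizes and runtime choices

Simulation-based checks use sequences of 300–2000 s at envelope rates of
500–1000 Hz; full-pipeline audio checks use 90–340 s of 44.1 kHz audio
(the acceptance run generates $\ge 300$ vocalizations); moment-recovery
checks use $10^5$ draws. These sizes put Monte-Carlo error comfortably
inside the stated tolerances while keeping a full run in minutes on one
CPU.

## Known limitations

* Single analysis band per run; no cochlear/gammatone front end.
* One pulse per detected segment; overlapping callers are not separated.
* The closed form's low-frequency regime degrades at high duty cycles
  (see above) — a property of the independence assumption, not of the
  estimator.
* Exponential duration distributions are matched by mean only (a one-
  parameter family cannot match an arbitrary mean/sd pair); the realized
  sd is whatever the mean implies.
* WAV I/O covers mono PCM16/PCM32/float32 (multi-channel files are
  averaged down).
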