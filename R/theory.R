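#' Parameters of the closed-form pulse-train modulation spectrum
#'
#' Collects what the shot-noise theory needs: the vocalization rate
#' `lambda`, the amplitude second moment `E[A^2] = mu_A^2 + sigma_A^2`, and
#' the duration distribution, either as a uniform support `[T1, T2]` or as
#' an empirical sample of durations (in which case expectations over the
#' duration distribution are evaluated by averaging over the sample).
#'
#' @param rate Vocalization rate lambda, /s.
#' @param amp_mean,amp_sd Amplitude moments (alternatively give
#'   `amp_second_moment` directly).
#' @param amp_second_moment `E[A^2]`; overrides `amp_mean`/`amp_sd`.
#' @param T1,T2 Uniform duration support, s (`T1 == T2` collapses to a
#'   single fixed duration).
#' @param durations Optional numeric sample of durations, s (used instead
#'   of the uniform support).
#' @return A `theory_params` list.
#' @export
theory_params <- function(rate, amp_mean = 1, amp_sd = 0,
                          amp_second_moment = NULL,
                          T1 = NULL, T2 = NULL, durations = NULL) {
  if (rate <= 0) abort("`rate` must be positive.")
  a2 <- if (!is.null(amp_second_moment)) amp_second_moment
        else amp_mean^2 + amp_sd^2
  if (a2 <= 0) abort("Amplitude second moment must be positive.")
  if (is.null(durations)) {
    if (is.null(T1) || is.null(T2)) abort("Give `T1`,`T2` or `durations`.")
    if (T1 < 0 || T2 < T1) abort("Need 0 <= T1 <= T2.")
  } else {
    if (any(durations < 0)) abort("Durations must be >= 0.")
  }
  structure(list(rate = rate, amp_second_moment = a2,
                 T1 = T1, T2 = T2, durations = durations),
            class = "theory_params")
}

#' Modulation power spectrum of a single rectangular pulse
#'
#' `A^2 sin^2(pi D f) / (pi^2 f^2)`, the squared Fourier magnitude of a
#' rectangular pulse of amplitude `A` and duration `D`, with the analytic
#' `f -> 0` limit `A^2 D^2`. This is the `sinc^2` building block whose
#' ensemble average over variable durations produces the dual-regime
#' lowpass spectrum.
#'
#' @param f Modulation frequency (Hz), vectorized.
#' @param amplitude Pulse amplitude `A`.
#' @param duration Pulse duration `D`, s.
#' @return Power at each `f`.
#' @export
single_pulse_spectrum <- function(f, amplitude = 1, duration = 1) {
  stopifnot(all(f >= 0))
  n <- max(length(f), length(amplitude), length(duration))
  f <- rep_len(f, n)
  amplitude <- rep_len(amplitude, n)
  duration <- rep_len(duration, n)
  out <- numeric(n)
  z <- f == 0
  out[z] <- (amplitude^2 * duration^2)[z]
  out[!z] <- (amplitude^2 * sin(pi * duration * f)^2 / (pi^2 * f^2))[!z]
  out
}

# E[sin^2(pi D f)] / (pi^2 f^2) for uniform D on [T1,T2], stable at small f.
uniform_duration_kernel <- function(f, T1, T2) {
  if (T2 == T1) return(single_pulse_spectrum(f, 1, T1))
  out <- numeric(length(f))
  u <- pi * f * (T2 - T1)
  v <- pi * f * (T1 + T2)
  small <- pi * f * T2 < 1e-3
  # bracket = 1 - cos(v) * sinc(u); series for small arguments
  br <- numeric(length(f))
  s <- small
  br[s] <- (v[s]^2 / 2 + u[s]^2 / 6) -
    (v[s]^4 / 24 + u[s]^4 / 120 + v[s]^2 * u[s]^2 / 12)
  b <- !small
  br[b] <- 1 - cos(v[b]) * ifelse(u[b] == 0, 1, sin(u[b]) / u[b])
  out <- br / (2 * pi^2 * f^2)
  out[f == 0] <- (T2^2 + T1 * T2 + T1^2) / 3
  out
}

#' Closed-form AMPS of the stochastic pulse-train model
#'
#' For independent, serially uncorrelated pulse parameters the model AMPS
#' is `lambda * E[A^2] * E[sin^2(pi D f)] / (pi^2 f^2)` (a two-sided
#' density). With uniform durations on `[T1, T2]` the expectation has the
#' closed form
#' `1/(2 pi^2 f^2) * [1 - (sin(2 pi T2 f) - sin(2 pi T1 f)) / ((T2-T1) 2 pi f)]`,
#' continuous at `f = 0` where it equals
#' `lambda E[A^2] (T2^2 + T1 T2 + T1^2)/3`. With an empirical duration
#' sample the expectation is evaluated by averaging the single-pulse
#' spectra. To overlay on a one-sided measured AMPS, double it (see
#' [theory_overlay()]).
#'
#' @param f Modulation frequency (Hz), vectorized, `f >= 0`.
#' @param p A [theory_params()].
#' @return Power density at each `f`.
#' @export
closed_form_amps <- function(f, p) {
  stopifnot(inherits(p, "theory_params"), all(f >= 0))
  pref <- p$rate * p$amp_second_moment
  if (!is.null(p$durations)) {
    d <- p$durations
    kern <- vapply(f, function(fi) {
      mean(single_pulse_spectrum(fi, 1, d))
    }, numeric(1))
    return(pref * kern)
  }
  pref * uniform_duration_kernel(f, p$T1, p$T2)
}

#' Closed-form AMPS as a one-sided spectrum tibble
#'
#' Evaluates [closed_form_amps()] on a frequency grid and doubles it so it
#' overlays directly on the one-sided multitaper AMPS.
#'
#' @param p A [theory_params()].
#' @param freq Frequency grid (Hz), or an `amps_spectrum` whose grid to use.
#' @return An `amps_spectrum` tibble.
#' @export
theory_overlay <- function(p, freq) {
  if (inherits(freq, "amps_spectrum")) freq <- freq$freq
  pow <- closed_form_amps(freq, p)
  pow[freq > 0] <- 2 * pow[freq > 0]
  new_amps_spectrum(freq, pow, rate = NA_real_, nfft = NA_integer_,
                    kind = "theory")
}

#' Low-frequency limit of the model AMPS
#'
#' `lambda E[A^2] E[D^2]`, the flat plateau value as `f -> 0` (for uniform
#' durations `E[D^2] = (T2^2 + T1 T2 + T1^2)/3`).
#'
#' @param p A [theory_params()].
#' @return Power density at `f = 0`.
#' @export
amps_low_limit <- function(p) {
  stopifnot(inherits(p, "theory_params"))
  d2 <- if (!is.null(p$durations)) mean(p$durations^2)
        else (p$T2^2 + p$T1 * p$T2 + p$T1^2) / 3
  p$rate * p$amp_second_moment * d2
}

#' High-frequency 1/f^2 asymptote of the model AMPS
#'
#' `lambda E[A^2] / (2 pi^2 f^2)`: the scale-invariant regime with
#' power-law exponent alpha = 2.
#'
#' @param f Modulation frequency (Hz), `f > 0`, vectorized.
#' @param p A [theory_params()].
#' @return Power density at each `f`.
#' @export
amps_high_asymptote <- function(f, p) {
  stopifnot(inherits(p, "theory_params"), all(f > 0))
  p$rate * p$amp_second_moment / (2 * pi^2 * f^2)
}

#' Cutoff frequency of the model AMPS
#'
#' The cutoff is the half-power (-3 dB) frequency relative to the AMPS at
#' zero frequency. `cutoff_approx()` is the closed-form approximation
#' `f_c ~ (1/pi) / sqrt(mu_D^2 + sigma_D^2) = (1/pi) / sqrt(E[D^2])`,
#' valid when `f_c > 1 / (2 pi (T2 - T1))`; `cutoff_numeric()` solves
#' `S(f_c) = S(0)/2` exactly by bisection in `log f` on 1e-3 to 1e3 Hz and
#' serves as the oracle for the approximation.
#'
#' @param duration_mean,duration_sd Duration moments, s.
#' @return Cutoff frequency, Hz.
#' @export
cutoff_approx <- function(duration_mean, duration_sd = 0) {
  if (any(duration_mean <= 0)) abort("`duration_mean` must be positive.")
  (1 / pi) / sqrt(duration_mean^2 + duration_sd^2)
}

#' @rdname cutoff_approx
#' @param p A [theory_params()].
#' @export
cutoff_numeric <- function(p) {
  stopifnot(inherits(p, "theory_params"))
  target <- amps_low_limit(p) / 2
  g <- function(lf) closed_form_amps(10^lf, p) - target
  lo <- -3; hi <- 3
  if (g(lo) < 0 || g(hi) > 0) {
    abort(sprintf(
      "Bisection bracket failure: S(1e-3)-S0/2 = %.3g, S(1e3)-S0/2 = %.3g.",
      g(lo), g(hi)))
  }
  # S is not monotone through the sinc ripples; bisection still converges
  # to a half-power crossing, which is unique for the uniform-duration form
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  10^((lo + hi) / 2)
}
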