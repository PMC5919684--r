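#' Simulate the stochastic pulse-train envelope model
#'
#' Draws a pulse sequence from the sequence model and renders its
#' piecewise-constant envelope on a sample grid.
#'
#' @param params A [seq_model_params()].
#' @param total_duration Sequence length T, s.
#' @param rate Envelope sample rate, Hz.
#' @param seed Optional integer seed.
#' @return A list with `seq` (the [pulse_seq()]) and `envelope` (an
#'   [envelope_signal()]).
#' @export
simulate_envelope <- function(params, total_duration, rate = 1000,
                              seed = NULL) {
  seq <- draw_pulse_sequence(params, total_duration, seed = seed)
  list(seq = seq, envelope = render_model_envelope(seq, rate))
}

#' Perturb a pulse sequence (amplitude / interval / duration manipulations)
#'
#' The four perturbations used to isolate which temporal cue produces the
#' 1/f^2 modulation spectrum:
#'
#' * `constant_amplitude`: every pulse gets the single amplitude that makes
#'   the perturbed envelope's variance equal the original envelope's
#'   variance (onsets and durations untouched).
#' * `constant_interval`: onsets are rewritten to a strict 1-per-`interval`
#'   grid (default 1 s); durations are capped at `0.9 * interval` (with a
#'   warning if any get truncated); amplitudes untouched. The sequence
#'   length grows to fit all pulses if necessary.
#' * `zero_duration`: durations set to zero; pulses become single-sample
#'   impulses of their original amplitudes at rendering.
#' * `swap_duration_dist`: durations redrawn from `target_dist` with the
#'   empirical mean and variance of the original durations (method of
#'   moments); overlaps resolved by redraw then truncation.
#'
#' @param seq A non-empty [pulse_seq()].
#' @param mode One of `"constant_amplitude"`, `"constant_interval"`,
#'   `"zero_duration"`, `"swap_duration_dist"`.
#' @param interval Constant inter-onset interval, s (for
#'   `constant_interval`).
#' @param target_dist Replacement duration distribution (for
#'   `swap_duration_dist`): `"uniform"`, `"exponential"`, or `"gamma"`.
#' @param seed Optional integer seed (used by `swap_duration_dist`).
#' @return A perturbed [pulse_seq()].
#' @export
perturb <- function(seq, mode = c("constant_amplitude", "constant_interval",
                                  "zero_duration", "swap_duration_dist"),
                    interval = 1, target_dist = c("uniform", "exponential",
                                                  "gamma"), seed = NULL) {
  stopifnot(inherits(seq, "pulse_seq"))
  mode <- match.arg(mode)
  if (nrow(seq) == 0L) abort("Cannot perturb an empty sequence.")
  T <- attr(seq, "total_duration")
  if (mode == "constant_amplitude") {
    # match the analytic variance of the rendered non-overlapping pulse
    # train: E[x^2] - E[x]^2 with E[x^k] = sum(A^k D)/T
    q <- sum(seq$duration) / T
    v0 <- sum(seq$amplitude^2 * seq$duration) / T -
      (sum(seq$amplitude * seq$duration) / T)^2
    if (q <= 0 || q >= 1) abort("Degenerate duty cycle; cannot match variance.")
    a <- sqrt(v0 / (q - q^2))
    return(pulse_seq(seq$onset, seq$duration, rep(a, nrow(seq)), T))
  }
  if (mode == "constant_interval") {
    n <- nrow(seq)
    onset <- (seq_len(n)) * interval
    dur <- seq$duration
    cap <- 0.9 * interval
    if (any(dur > cap)) {
      warn(sprintf("%d duration(s) truncated to 0.9 * interval.",
                   sum(dur > cap)))
      dur <- pmin(dur, cap)
    }
    T_new <- max(T, (n + 1) * interval)
    return(pulse_seq(onset, dur, seq$amplitude, T_new))
  }
  if (mode == "zero_duration") {
    return(pulse_seq(seq$onset, rep(0, nrow(seq)), seq$amplitude, T))
  }
  # swap_duration_dist
  target_dist <- match.arg(target_dist)
  if (!is.null(seed)) set.seed(seed)
  m <- mean(seq$duration); s <- sd(seq$duration)
  if (target_dist == "uniform" && m - sqrt(3) * s < 0) {
    abort("Uniform target with these moments would need negative durations.")
  }
  n <- nrow(seq)
  gap <- c(diff(seq$onset), T - seq$onset[n])
  dur <- draw_dist(n, target_dist, m, s)
  for (i in 1:100) {
    bad <- which(dur > gap)
    if (length(bad) == 0L) break
    dur[bad] <- draw_dist(length(bad), target_dist, m, s)
  }
  dur <- pmin(dur, gap)
  pulse_seq(seq$onset, dur, seq$amplitude, T)
}

#' Run a set of perturbation experiments
#'
#' Simulates a baseline sequence, applies each requested perturbation,
#' computes the multitaper AMPS of each rendered envelope, and fits the
#' scaling exponent and lowpass cutoff.
#'
#' @param params A [seq_model_params()].
#' @param total_duration Sequence length, s.
#' @param modes Character vector of perturbation modes (see [perturb()]);
#'   the unperturbed baseline is always included as mode `"baseline"`.
#' @param rate Envelope sample rate, Hz.
#' @param seed Integer seed.
#' @param nfft Transform length for most modes.
#' @param nfft_hires Transform length used for `constant_interval`, whose
#'   dense harmonic structure needs finer frequency resolution.
#' @param interval Constant interval, s.
#' @param target_dist Swap target distribution.
#' @param scaling_range,lowpass_range Fit ranges, Hz.
#' @return A tibble with one row per mode: `mode`, `alpha`, `f_c`,
#'   `rms_residual_db`, and list-columns `spectrum`, `scaling_fit`,
#'   `lowpass_fit`, `seq`.
#' @export
perturbation_experiment <- function(params, total_duration,
                                    modes = c("constant_amplitude",
                                              "constant_interval",
                                              "zero_duration",
                                              "swap_duration_dist"),
                                    rate = 1000, seed = 1L, nfft = 16384,
                                    nfft_hires = 262144, interval = 1,
                                    target_dist = "gamma",
                                    scaling_range = c(20, 200),
                                    lowpass_range = c(0.1, 100)) {
  base <- simulate_envelope(params, total_duration, rate = rate, seed = seed)
  seqs <- c(list(baseline = base$seq),
            purrr::map(rlang::set_names(modes), function(m) {
              perturb(base$seq, mode = m, interval = interval,
                      target_dist = target_dist, seed = seed + 1L)
            }))
  purrr::map_dfr(names(seqs), function(nm) {
    sq <- seqs[[nm]]
    nf <- if (identical(nm, "constant_interval")) nfft_hires else nfft
    env <- render_model_envelope(sq, rate)
    sp <- multitaper_amps(env, nfft = nf)
    sf <- fit_scaling_exponent(sp, fit_range = scaling_range)
    lf <- fit_lowpass(sp, fit_range = lowpass_range)
    tibble(mode = nm, alpha = sf$exponent, f_c = lf$cutoff,
           rms_residual_db = lf$rms_residual_db,
           spectrum = list(sp), scaling_fit = list(sf),
           lowpass_fit = list(lf), seq = list(sq))
  })
}
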