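#' Stochastic vocalization-sequence model parameters
#'
#' Distributional description of a vocalization sequence: rate, pulse
#' amplitude moments, pulse duration distribution and moments, and the
#' inter-onset interval model (a dead-time-shifted exponential, reproducing
#' the refractory gap plus exponential-like tail seen in inter-vocalization
#' interval histograms).
#'
#' Moments are matched by the method of moments:
#' * `uniform` durations on `[T1, T2]` with `T1 = mean - sqrt(3) sd`,
#'   `T2 = mean + sqrt(3) sd` (requires `T1 >= 0`);
#' * `gamma` with `shape = (mean/sd)^2`, `rate = mean/sd^2`;
#' * `exponential` matches the mean only (its sd is then equal to the mean);
#' * `fixed` ignores the sd.
#'
#' The interval model is resolved as follows: if `interval_mean` is missing
#' it is taken as `1/rate`; if `interval_dead_time` is missing it is
#' `max(interval_mean - interval_sd, 0)` when `interval_sd` is given, else 0.
#' Sequences place a silent gap of `dead_time + Exp(...)` after each pulse
#' (see [draw_pulse_sequence()]), with the exponential mean chosen so the
#' onset-to-onset interval mean is `interval_mean` and the mean
#' vocalization rate is `1/interval_mean`.
#'
#' @param rate Mean vocalization rate lambda, vocalizations/s.
#' @param amplitude_mean,amplitude_sd Pulse amplitude moments (envelope units).
#' @param amplitude_dist One of `"gamma"`, `"lognormal"`, `"fixed"`.
#' @param duration_mean,duration_sd Pulse duration moments, s.
#' @param duration_dist One of `"uniform"`, `"exponential"`, `"gamma"`,
#'   `"fixed"`.
#' @param interval_mean,interval_sd Inter-onset interval moments, s
#'   (optional; see Details).
#' @param interval_dead_time Refractory gap between consecutive onsets, s.
#' @return A `seq_model_params` list.
#' @export
#' @examples
#' seq_model_params(rate = 2, amplitude_mean = 1, amplitude_sd = 0,
#'                  duration_mean = 0.275, duration_sd = 0.13,
#'                  duration_dist = "uniform")
seq_model_params <- function(rate = NULL,
                             amplitude_mean = 1, amplitude_sd = 0,
                             amplitude_dist = c("gamma", "lognormal", "fixed"),
                             duration_mean = 0.2, duration_sd = 0.1,
                             duration_dist = c("uniform", "exponential",
                                               "gamma", "fixed"),
                             interval_mean = NULL, interval_sd = NULL,
                             interval_dead_time = NULL) {
  amplitude_dist <- match.arg(amplitude_dist)
  duration_dist <- match.arg(duration_dist)
  if (amplitude_sd == 0) amplitude_dist <- "fixed"
  if (duration_sd == 0 && duration_dist != "exponential")
    duration_dist <- "fixed"
  if (is.null(rate) && is.null(interval_mean)) {
    abort("Provide `rate` and/or `interval_mean`.")
  }
  if (is.null(interval_mean)) interval_mean <- 1 / rate
  if (is.null(rate)) rate <- 1 / interval_mean
  if (is.null(interval_dead_time)) {
    interval_dead_time <-
      if (!is.null(interval_sd)) max(interval_mean - interval_sd, 0) else 0
  }
  if (is.null(interval_sd)) interval_sd <- interval_mean - interval_dead_time
  if (rate <= 0) abort("`rate` must be positive.")
  if (duration_mean <= 0) abort("`duration_mean` must be positive.")
  if (duration_sd < 0 || amplitude_sd < 0) abort("sd values must be >= 0.")
  if (amplitude_mean <= 0) abort("`amplitude_mean` must be positive.")
  if (interval_dead_time < 0) abort("`interval_dead_time` must be >= 0.")
  if (interval_mean - interval_dead_time <= 0) {
    abort("`interval_mean` must exceed `interval_dead_time`.")
  }
  if (duration_dist == "uniform") {
    t1 <- duration_mean - sqrt(3) * duration_sd
    if (t1 < 0) {
      abort(paste0("Infeasible uniform duration distribution: ",
                   "T1 = mean - sqrt(3)*sd = ", signif(t1, 4), " < 0."))
    }
  }
  structure(list(rate = rate,
                 amplitude_mean = amplitude_mean,
                 amplitude_sd = amplitude_sd,
                 amplitude_dist = amplitude_dist,
                 duration_mean = duration_mean,
                 duration_sd = duration_sd,
                 duration_dist = duration_dist,
                 interval_mean = interval_mean,
                 interval_sd = interval_sd,
                 interval_dead_time = interval_dead_time),
            class = "seq_model_params")
}

#' Uniform duration support implied by the moments
#' @param params A [seq_model_params()] with `duration_dist = "uniform"`.
#' @return Numeric `c(T1, T2)`.
#' @export
duration_support <- function(params) {
  stopifnot(inherits(params, "seq_model_params"))
  c(params$duration_mean - sqrt(3) * params$duration_sd,
    params$duration_mean + sqrt(3) * params$duration_sd)
}

# method-of-moments draws for the named distributions
draw_dist <- function(n, dist, mean, sd) {
  if (n == 0L) return(numeric(0))
  switch(dist,
    fixed = rep(mean, n),
    uniform = runif(n, mean - sqrt(3) * sd, mean + sqrt(3) * sd),
    exponential = rexp(n, rate = 1 / mean),
    gamma = rgamma(n, shape = (mean / sd)^2, rate = mean / sd^2),
    lognormal = {
      s2 <- log(1 + (sd / mean)^2)
      stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
    },
    abort(sprintf("Unknown distribution '%s'.", dist)))
}

#' Pulse sequence container
#'
#' A tibble of non-overlapping rectangular pulses, one row per vocalization,
#' with columns `onset`, `duration`, `amplitude` (seconds, seconds, envelope
#' units), carrying the sequence length as an attribute. This is both the
#' generator's ground truth and the output of the pulse-fitting stage.
#'
#' @param onset,duration,amplitude Numeric vectors of equal length.
#' @param total_duration Sequence length T in seconds.
#' @return A `pulse_seq` tibble.
#' @export
pulse_seq <- function(onset = numeric(), duration = numeric(),
                      amplitude = numeric(), total_duration) {
  stopifnot(length(onset) == length(duration),
            length(onset) == length(amplitude))
  if (is.unsorted(onset)) {
    o <- order(onset)
    onset <- onset[o]; duration <- duration[o]; amplitude <- amplitude[o]
  }
  if (any(duration < 0)) abort("Durations must be >= 0.")
  n <- length(onset)
  if (n > 1L && any(onset[-n] + duration[-n] > onset[-1L] + 1e-12)) {
    abort("Pulses overlap: need onset[n] + duration[n] <= onset[n+1].")
  }
  out <- tibble(onset = as.numeric(onset), duration = as.numeric(duration),
                amplitude = as.numeric(amplitude))
  class(out) <- c("pulse_seq", class(out))
  attr(out, "total_duration") <- as.numeric(total_duration)
  out
}

#' @export
#' @rdname pulse_seq
#' @param seq A `pulse_seq`.
total_duration <- function(seq) attr(seq, "total_duration")

#' @export
#' @rdname pulse_seq
voc_rate <- function(seq) nrow(seq) / attr(seq, "total_duration")

#' Draw a random pulse sequence from the stochastic vocalization model
#'
#' Durations and amplitudes are i.i.d. draws from the configured
#' distributions. Non-overlap is enforced by construction: each pulse is
#' followed by a silent gap equal to the refractory dead time plus an
#' exponential draw whose mean is `interval_mean - duration_mean -
#' dead_time`, so the onset-to-onset intervals have mean `interval_mean`
#' (hence `E[N] ~ rate * T`), a hard refractory region, and an
#' exponential-like tail, while the drawn duration marginals are preserved
#' exactly (a draw-then-truncate scheme would shorten the durations
#' whenever gaps are comparable to durations, biasing the duration mean by
#' tens of percent at realistic duty cycles). Only the last pulse can be
#' truncated, against the end of the sequence; the count is recorded in the
#' `n_truncated` attribute.
#'
#' @param params A [seq_model_params()]; `interval_mean` must exceed
#'   `duration_mean + interval_dead_time`, otherwise the requested moments
#'   are infeasible and an error is raised.
#' @param total_duration Sequence length T in seconds.
#' @param seed Optional integer seed for reproducibility.
#' @return A [pulse_seq()] with `N` approximately `rate * total_duration`.
#' @export
draw_pulse_sequence <- function(params, total_duration, seed = NULL) {
  stopifnot(inherits(params, "seq_model_params"))
  if (total_duration < 0) abort("`total_duration` must be >= 0.")
  if (!is.null(seed)) set.seed(seed)
  if (total_duration == 0) {
    return(pulse_seq(total_duration = 0))
  }
  dead <- params$interval_dead_time
  mu_gap <- params$interval_mean - params$duration_mean - dead
  if (mu_gap <= 0) {
    abort(paste0("Infeasible moments: interval_mean must exceed ",
                 "duration_mean + interval_dead_time."))
  }
  # draw (duration, gap) pairs in blocks until the sequence passes T
  expected <- as.integer(ceiling(total_duration / params$interval_mean) + 10L)
  dur <- numeric(0); gap <- numeric(0)
  repeat {
    dur <- c(dur, draw_dist(expected, params$duration_dist,
                            params$duration_mean, params$duration_sd))
    gap <- c(gap, dead + rexp(expected, rate = 1 / mu_gap))
    if (sum(dur) + sum(gap) > total_duration) break
  }
  onsets <- cumsum(c(gap[1], dur[-length(dur)] + gap[-1]))
  keep <- onsets < total_duration
  onsets <- onsets[keep]; dur <- dur[seq_along(onsets)]
  n <- length(onsets)
  if (n == 0L) return(pulse_seq(total_duration = total_duration))
  n_trunc <- 0L
  if (onsets[n] + dur[n] > total_duration) {
    dur[n] <- total_duration - onsets[n]
    n_trunc <- 1L
  }
  amp <- draw_dist(n, params$amplitude_dist, params$amplitude_mean,
                   params$amplitude_sd)
  out <- pulse_seq(onsets, dur, amp, total_duration)
  attr(out, "n_truncated") <- n_trunc
  out
}

#' Synthetic vocalization scene specification
#'
#' Describes how to turn a ground-truth pulse sequence into audio: a
#' band-limited carrier (Gaussian noise filtered to `carrier_band`, or a
#' tone at the band center) is multiplied by the piecewise-constant pulse
#' envelope, optionally further modulated by a periodic vocal-fold-like
#' component `1 + depth * cos(2 pi f0 t)`, and added to a stationary white
#' noise floor whose power is set by `snr_db` relative to the rendered
#' vocal signal power (or given directly as `noise_floor_sd`).
#'
#' @param carrier_band Numeric `c(f_low, f_high)` in Hz.
#' @param sample_rate Audio sampling rate Fs, Hz.
#' @param total_duration Scene length, s.
#' @param snr_db Signal-to-noise ratio in dB (vocal power over noise power).
#' @param vocal_fold_f0 Fundamental of the periodic envelope modulation, Hz,
#'   or `NULL` for none.
#' @param vocal_fold_depth Modulation depth of the periodic component.
#' @param carrier `"noise"` or `"tone"`.
#' @param noise_floor_sd Optional explicit noise floor sd (overrides
#'   `snr_db`).
#' @param seed Integer seed making the render reproducible.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(carrier_band, sample_rate, total_duration,
                       snr_db = 30, vocal_fold_f0 = NULL,
                       vocal_fold_depth = 0.5,
                       carrier = c("noise", "tone"),
                       noise_floor_sd = NULL, seed = 1L) {
  carrier <- match.arg(carrier)
  if (length(carrier_band) != 2L || carrier_band[1] <= 0 ||
      carrier_band[2] <= carrier_band[1] ||
      carrier_band[2] >= sample_rate / 2) {
    abort("`carrier_band` must satisfy 0 < f_low < f_high < sample_rate/2.")
  }
  if (total_duration <= 0) abort("`total_duration` must be positive.")
  structure(list(carrier_band = as.numeric(carrier_band),
                 sample_rate = as.numeric(sample_rate),
                 total_duration = as.numeric(total_duration),
                 snr_db = as.numeric(snr_db),
                 vocal_fold_f0 = vocal_fold_f0,
                 vocal_fold_depth = vocal_fold_depth,
                 carrier = carrier,
                 noise_floor_sd = noise_floor_sd,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Render a synthetic vocalization scene to audio
#'
#' Deterministic given `spec$seed`. The carrier is scaled so that the
#' smoothed Hilbert envelope of a pulse of amplitude `A` is approximately
#' `A` (for the noise carrier this uses the Rayleigh envelope mean
#' `sd * sqrt(pi/2)` of narrowband Gaussian noise).
#'
#' @param spec A [scene_spec()].
#' @param truth A [pulse_seq()] fitting inside `spec$total_duration`.
#' @return A [waveform()] of length `total_duration * sample_rate`.
#' @export
render_scene <- function(spec, truth) {
  stopifnot(inherits(spec, "scene_spec"), inherits(truth, "pulse_seq"))
  if (nrow(truth) > 0 &&
      max(truth$onset + truth$duration) > spec$total_duration + 1e-9) {
    abort("`truth` does not fit inside the scene duration.")
  }
  fs <- spec$sample_rate
  n <- as.integer(round(spec$total_duration * fs))
  set.seed(spec$seed)
  if (spec$carrier == "noise") {
    h <- kaiser_bandpass(fs, spec$carrier_band[1], spec$carrier_band[2])
    carrier <- fir_apply(rnorm(n), h)
    carrier <- carrier / (sd(carrier) * sqrt(pi / 2))
  } else {
    fc <- sqrt(prod(spec$carrier_band))
    carrier <- cos(2 * pi * fc * (seq_len(n) - 1) / fs)
  }
  env <- render_model_envelope(truth, fs, n_samples = n)$samples
  if (!is.null(spec$vocal_fold_f0)) {
    t <- (seq_len(n) - 1) / fs
    env <- env * (1 + spec$vocal_fold_depth *
                    cos(2 * pi * spec$vocal_fold_f0 * t))
  }
  sig <- carrier * env
  sigma_n <- if (!is.null(spec$noise_floor_sd)) {
    spec$noise_floor_sd
  } else {
    p_sig <- mean(sig^2)
    if (p_sig == 0) 1e-3 else sqrt(p_sig / 10^(spec$snr_db / 10))
  }
  waveform(sig + sigma_n * rnorm(n), fs)
}

#' Per-species synthesis presets
#'
#' Named presets bundling the recording settings (sampling rate, analysis
#' band, decimation factor, segmentation threshold) and the fitted sequence
#' statistics (rate, amplitude/duration/interval moments) of each studied
#' vocalization group: `"rat"`, `"mouse"`, `"bird"`, `"monkey"`, `"infant"`,
#' `"speech"`. Durations and amplitudes use gamma distributions with the
#' tabulated moments; intervals are dead-time-shifted exponentials.
#'
#' @param species Preset name.
#' @return A list with elements `params` (a [seq_model_params()]), `F_s`,
#'   `DF`, `T_x`, `f_low`, `f_high`.
#' @export
#' @examples
#' p <- species_preset("infant")
#' p$params$rate
species_preset <- function(species = c("rat", "mouse", "bird", "monkey",
                                       "infant", "speech")) {
  species <- match.arg(species)
  tab <- list(
    #              F_s     DF  T_x  f_lo    f_hi    muA  sdA   muD   sdD   muI  sdI  lam
    rat    = list(250e3, 100L, 10, 30e3, 100e3, 0.86, 2.14, 0.036, 0.039, 0.63, 0.82, 1.59),
    mouse  = list(300e3, 100L, 30, 30e3, 100e3, 1.22, 3.66, 0.013, 0.011, 0.60, 1.47, 1.65),
    bird   = list(44.1e3, 10L, 30, 500, 20e3, 1.51, 1.16, 0.14, 0.37, 0.57, 1.29, 1.74),
    monkey = list(44.1e3, 10L, 30, 500, 20e3, 1.14, 0.86, 0.14, 0.21, 0.53, 0.76, 1.89),
    infant = list(44.1e3, 10L, 30, 500, 20e3, 1.58, 1.02, 0.33, 0.20, 1.06, 0.99, 0.94),
    speech = list(44.1e3, 10L, 10, 500, 20e3, 0.84, 0.72, 0.22, 0.27, 0.37, 0.36, 2.68)
  )[[species]]
  names(tab) <- c("F_s", "DF", "T_x", "f_low", "f_high", "muA", "sdA",
                  "muD", "sdD", "muI", "sdI", "lambda")
  params <- seq_model_params(
    rate = tab$lambda,
    amplitude_mean = tab$muA, amplitude_sd = tab$sdA,
    amplitude_dist = "gamma",
    duration_mean = tab$muD, duration_sd = tab$sdD,
    duration_dist = "gamma",
    interval_mean = tab$muI, interval_sd = tab$sdI)
  list(species = species, params = params, F_s = tab$F_s, DF = tab$DF,
       T_x = tab$T_x, f_low = tab$f_low, f_high = tab$f_high)
}

#' Generate a complete synthetic scene for a species preset
#'
#' Draws a ground-truth pulse sequence from the preset's sequence model and
#' renders it with the preset's recording settings.
#'
#' @param species Preset name (see [species_preset()]).
#' @param total_duration Scene length, s.
#' @param snr_db Signal-to-noise ratio, dB.
#' @param seed Integer seed.
#' @param sample_rate Optional override of the preset sampling rate.
#' @return A list with `truth` (a [pulse_seq()]), `audio` (a [waveform()]),
#'   `spec` (the [scene_spec()]) and `preset`.
#' @export
synth_scene <- function(species, total_duration, snr_db = 30, seed = 1L,
                        sample_rate = NULL) {
  preset <- species_preset(species)
  fs <- if (is.null(sample_rate)) preset$F_s else sample_rate
  truth <- draw_pulse_sequence(preset$params, total_duration, seed = seed)
  spec <- scene_spec(carrier_band = c(preset$f_low, preset$f_high),
                     sample_rate = fs, total_duration = total_duration,
                     snr_db = snr_db, seed = seed + 1L)
  list(truth = truth, audio = render_scene(spec, truth), spec = spec,
       preset = preset)
}

#' Write a synthetic scene to disk
#'
#' Writes a float32 WAV, a ground-truth CSV (`onset_s, duration_s,
#' amplitude`) and a JSON manifest of the scene parameters.
#'
#' @param scene A list as returned by [synth_scene()].
#' @param dir Output directory (created if needed).
#' @param name Base file name.
#' @return The directory path, invisibly.
#' @export
write_scene <- function(scene, dir, name = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_wav(scene$audio, file.path(dir, paste0(name, ".wav")))
  gt <- scene$truth
  utils::write.csv(
    data.frame(onset_s = gt$onset, duration_s = gt$duration,
               amplitude = gt$amplitude),
    file.path(dir, paste0(name, "_truth.csv")), row.names = FALSE)
  manifest <- scene$spec
  class(manifest) <- NULL
  manifest$species <- scene$preset$species
  jsonlite::write_json(manifest, file.path(dir, paste0(name, ".json")),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}
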