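# Shared fixture builders. Everything is generated in code; scenes use low
# sampling rates where the full audio chain is exercised but kept cheap.

tone_waveform <- function(freq, fs = 8000, dur = 2, amp = 1) {
  t <- (0:(round(dur * fs) - 1)) / fs
  waveform(amp * cos(2 * pi * freq * t), fs)
}

# a small rendered scene with well-separated identical pulses and a
# guaranteed noise-only lead-in; returns truth, audio and envelopes
toy_scene <- function(n_pulses = 10, amp = 1, dur = 0.3, gap = 1.2,
                      fs = 8000, band = c(500, 3500), snr_db = 40,
                      seed = 1) {
  onset <- 3 + (seq_len(n_pulses) - 1) * (dur + gap)
  total <- max(onset) + dur + 1
  truth <- pulse_seq(onset, rep(dur, n_pulses), rep(amp, n_pulses), total)
  spec <- scene_spec(band, fs, total, snr_db = snr_db, seed = seed)
  audio <- render_scene(spec, truth)
  env <- extract_envelopes(audio, band[1], band[2], DF = 2)
  list(truth = truth, audio = audio, env = env, spec = spec)
}

# rectangle-on-a-grid envelope for pulse-fit tests
rect_envelope <- function(rate = 1000, total = 1, onset = 0.3, dur = 0.3,
                          amp = 2, noise_sd = 0) {
  sq <- pulse_seq(onset, dur, amp, total)
  e <- render_model_envelope(sq, rate)
  if (noise_sd > 0) {
    e$samples <- e$samples + rnorm(length(e$samples), sd = noise_sd)
  }
  e
}

# default uniform-duration model used across simulation tests
unif_params <- function(rate = 0.5, dmean = 0.275, dsd = 0.45 / sqrt(12)) {
  seq_model_params(rate = rate, amplitude_mean = 1, amplitude_sd = 0,
                   duration_mean = dmean, duration_sd = dsd,
                   duration_dist = "uniform")
}

segment_tbl <- function(e, start_s, end_s) {
  tibble::tibble(start_index = as.integer(round(start_s * e$rate)) + 1L,
                 end_index = as.integer(round(end_s * e$rate)) + 1L,
                 start_s = start_s, end_s = end_s)
}
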