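#' Bandpass filter a waveform around its vocalization band
#'
#' Applies a Kaiser-windowed linear-phase FIR bandpass (default beta = 5.6,
#' order = 640, ~60 dB sidelobe attenuation), forward-only with the group
#' delay compensated so event times are preserved. The band is chosen to
#' cover the species' vocal energy (e.g. 30-100 kHz for rodent ultrasonic
#' calls, 0.5-20 kHz for speech, birds, monkeys, infant cries).
#'
#' @param w A [waveform()].
#' @param f_low,f_high Band edges in Hz; `0 < f_low < f_high < rate/2`.
#' @param order Filter order (number of taps minus one).
#' @param beta Kaiser window shape parameter.
#' @return A band-limited [waveform()].
#' @export
bandpass <- function(w, f_low, f_high, order = 640, beta = 5.6) {
  stopifnot(inherits(w, "waveform"))
  h <- kaiser_bandpass(w$rate, f_low, f_high, order = order, beta = beta)
  waveform(fir_apply(w$samples, h), w$rate)
}

#' Analytic-signal envelope of a band-limited waveform
#'
#' Computes the magnitude of the analytic signal `s + i H{s}` (Hilbert
#' construction in the frequency domain). Call [bandpass()] first: the
#' envelope is only meaningful for a band-limited carrier.
#'
#' @param w A band-limited [waveform()].
#' @return An [envelope_signal()] at the waveform's rate (no lowpass yet).
#' @export
analytic_envelope <- function(w) {
  stopifnot(inherits(w, "waveform"))
  envelope_signal(hilbert_envelope_vec(w$samples), w$rate)
}

#' Lowpass filter and decimate an envelope
#'
#' Two roles, matching the two envelopes used throughout the analysis:
#'
#' * the **analysis envelope**: a linear-phase FIR anti-alias lowpass
#'   (default 250 Hz cutoff), decimation by an integer factor `DF`, and
#'   scaling to unit standard deviation (`method = "fir"`, the default for
#'   cutoffs above 30 Hz);
#' * the **segmentation envelope**: a 5th-order B-spline lowpass (five-fold
#'   boxcar convolution, continuously differentiable response) with its
#'   -3 dB point at the cutoff (default 30 Hz), without rescaling
#'   (`method = "bspline"`, the default at cutoffs of 30 Hz and below).
#'
#' @param e An [envelope_signal()] (or [waveform()], treated sample-wise).
#' @param cutoff Lowpass cutoff in Hz.
#' @param DF Integer decimation factor; the output rate is `rate / DF`.
#' @param method `"fir"` or `"bspline"`; see above.
#' @param normalize Scale output to unit standard deviation. Defaults to
#'   `TRUE` for the FIR analysis path, `FALSE` for the B-spline path.
#' @return An [envelope_signal()] at rate `rate / DF`.
#' @export
lowpass_decimate <- function(e, cutoff, DF = 1L,
                             method = c("auto", "fir", "bspline"),
                             normalize = NULL) {
  stopifnot(inherits(e, c("envelope", "waveform")))
  method <- match.arg(method)
  if (method == "auto") method <- if (cutoff <= 30) "bspline" else "fir"
  if (is.null(normalize)) normalize <- (method == "fir")
  DF <- as.integer(DF)
  if (is.na(DF) || DF < 1L) abort("`DF` must be a positive integer.")
  new_rate <- e$rate / DF
  if (cutoff > new_rate / 2) {
    abort("`cutoff` exceeds the Nyquist frequency after decimation.")
  }
  x <- e$samples
  if (method == "fir") {
    # true lowpass at `cutoff` (transition to 1.5x cutoff), which also
    # anti-aliases any decimation since cutoff < new Nyquist
    if (cutoff < 0.98 * new_rate / 2 || DF > 1L) {
      stop_hz <- min(1.5 * cutoff, 0.999 * e$rate / 2)
      h <- kaiser_lowpass(e$rate, cutoff, stop_hz, atten_db = 60)
      x <- fir_apply(x, h)
      edge <- (length(h) - 1L) %/% 2L
    } else edge <- 0L
  } else {
    h <- bspline_kernel(e$rate, cutoff)
    x <- fir_apply(x, h)
    edge <- (length(h) - 1L) %/% 2L
  }
  if (DF > 1L) x <- x[seq(1L, length(x), by = DF)]
  if (normalize) {
    s <- sd(x)
    if (s == 0) abort("Cannot normalize a constant envelope to unit SD.")
    x <- x / s
  }
  envelope_signal(x, new_rate, lowpass_cutoff = cutoff,
                  normalized = isTRUE(normalize),
                  edge_samples = as.integer(ceiling(edge / DF)))
}

#' Extract the analysis and segmentation envelopes of a recording
#'
#' Convenience wrapper running the full envelope front end: bandpass to the
#' vocal band, analytic-signal magnitude, then (i) the 250 Hz FIR lowpass,
#' decimation by `DF` and unit-SD scaling (analysis envelope) and (ii) a
#' 30 Hz B-spline lowpass of the decimated envelope (segmentation envelope).
#'
#' @param w A [waveform()].
#' @param f_low,f_high Vocal band edges, Hz.
#' @param DF Decimation factor applied after the 250 Hz lowpass.
#' @param analysis_cutoff Analysis lowpass cutoff, Hz (default 250).
#' @param segmentation_cutoff Segmentation lowpass cutoff, Hz (default 30).
#' @return A list with elements `analysis` (unit-SD envelope at `rate/DF`)
#'   and `segmentation` (30 Hz B-spline envelope at the same rate, on the
#'   same scale as the unnormalized analysis envelope).
#' @export
extract_envelopes <- function(w, f_low, f_high, DF,
                              analysis_cutoff = 250,
                              segmentation_cutoff = 30) {
  wb <- bandpass(w, f_low, f_high)
  e_raw <- analytic_envelope(wb)
  e_unnorm <- lowpass_decimate(e_raw, analysis_cutoff, DF = DF,
                               method = "fir", normalize = FALSE)
  s <- sd(e_unnorm$samples)
  e250 <- envelope_signal(e_unnorm$samples / s, e_unnorm$rate,
                          lowpass_cutoff = analysis_cutoff,
                          normalized = TRUE,
                          edge_samples = e_unnorm$edge_samples)
  e30 <- lowpass_decimate(e_unnorm, segmentation_cutoff, DF = 1L,
                          method = "bspline", normalize = FALSE)
  list(analysis = e250, segmentation = e30, scale = s)
}

#' Export an envelope as CSV
#' @param e An [envelope_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_envelope_csv <- function(e, path) {
  utils::write.csv(as_tibble(e), path, row.names = FALSE)
  invisible(path)
}
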