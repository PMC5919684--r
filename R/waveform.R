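#' Sampled audio waveform
#'
#' Lightweight container for a single-channel sampled signal. Everything in
#' the package that touches audio starts from one of these.
#'
#' @param samples Numeric vector of samples.
#' @param rate Sampling rate in Hz.
#' @return An object of class `waveform` with fields `samples` and `rate`.
#' @export
#' @examples
#' w <- waveform(sin(2 * pi * 100 * seq(0, 1, by = 1 / 8000)), 8000)
#' duration(w)
waveform <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    abort("`rate` must be a single positive number (Hz).")
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    abort("`samples` must be finite and non-missing.")
  }
  structure(list(samples = samples, rate = as.numeric(rate)),
            class = "waveform")
}

#' Band-limited temporal envelope
#'
#' The magnitude of the analytic signal of a band-limited waveform, possibly
#' lowpass filtered, decimated, and scaled to unit standard deviation. Created
#' by [analytic_envelope()] and [lowpass_decimate()].
#'
#' @param samples Nonnegative numeric vector (before normalization).
#' @param rate Sampling rate in Hz (original rate divided by the decimation
#'   factor).
#' @param lowpass_cutoff Cutoff of the last lowpass filter applied, Hz, or
#'   `NA` if none.
#' @param normalized Logical; `TRUE` once scaled to unit standard deviation.
#' @param edge_samples Number of samples at each end affected by filter
#'   transients (excluded from noise statistics downstream).
#' @return An object of class `envelope`.
#' @export
envelope_signal <- function(samples, rate, lowpass_cutoff = NA_real_,
                            normalized = FALSE, edge_samples = 0L) {
  samples <- as.numeric(samples)
  if (rate <= 0) abort("`rate` must be positive.")
  structure(list(samples = samples, rate = as.numeric(rate),
                 lowpass_cutoff = as.numeric(lowpass_cutoff),
                 normalized = isTRUE(normalized),
                 edge_samples = as.integer(edge_samples)),
            class = "envelope")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g Hz (%.3f s)>\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

#' @export
print.envelope <- function(x, ...) {
  cat(sprintf(
    "<envelope: %d samples @ %g Hz, lowpass %s Hz%s>\n",
    length(x$samples), x$rate,
    ifelse(is.na(x$lowpass_cutoff), "-", format(x$lowpass_cutoff)),
    if (x$normalized) ", unit SD" else ""))
  invisible(x)
}

#' Duration of a signal in seconds
#' @param x A `waveform` or `envelope`.
#' @return Duration in seconds.
#' @export
duration <- function(x) {
  stopifnot(inherits(x, c("waveform", "envelope")))
  length(x$samples) / x$rate
}

#' Sample times of a signal
#' @param x A `waveform` or `envelope`.
#' @return Numeric vector of sample times in seconds (first sample at 0).
#' @export
sample_times <- function(x) {
  stopifnot(inherits(x, c("waveform", "envelope")))
  (seq_along(x$samples) - 1) / x$rate
}

#' @export
as_tibble.waveform <- function(x, ...) {
  tibble(time = sample_times(x), value = x$samples)
}

#' @export
as_tibble.envelope <- function(x, ...) {
  tibble(time = sample_times(x), value = x$samples)
}

# ---- WAV input/output --------------------------------------------------
# Minimal mono RIFF/WAVE support: PCM 16/32-bit and IEEE float32.

#' Read a mono WAV file
#'
#' Supports uncompressed PCM (16- or 32-bit) and IEEE float32; multi-channel
#' files are mixed down by averaging. PCM samples are rescaled to [-1, 1].
#'
#' @param path Path to a `.wav` file.
#' @return A [waveform()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort("Not a RIFF file.")
  readBin(con, "integer", 1, 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort("Not a WAVE file.")
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        format = readBin(fmt_raw[1:2], "integer", 1, 2, signed = FALSE,
                         endian = "little"),
        channels = readBin(fmt_raw[3:4], "integer", 1, 2, signed = FALSE,
                           endian = "little"),
        rate = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(fmt_raw[15:16], "integer", 1, 2, signed = FALSE,
                       endian = "little"))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size)
    }
    if (size %% 2 == 1) readBin(con, "raw", 1)  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) abort("Malformed WAV: missing chunk.")
  n_bytes <- fmt$bits %/% 8
  n <- length(data_raw) %/% n_bytes
  x <- if (fmt$format == 3L && fmt$bits == 32L) {
    readBin(data_raw, "double", n, size = 4, endian = "little")
  } else if (fmt$format == 1L && fmt$bits == 16L) {
    readBin(data_raw, "integer", n, size = 2, signed = TRUE,
            endian = "little") / 32768
  } else if (fmt$format == 1L && fmt$bits == 32L) {
    readBin(data_raw, "integer", n, size = 4, endian = "little") / 2147483648
  } else {
    abort(sprintf("Unsupported WAV encoding (format %d, %d bits).",
                  fmt$format, fmt$bits))
  }
  if (fmt$channels > 1L) {
    x <- colMeans(matrix(x, nrow = fmt$channels))
  }
  waveform(x, fmt$rate)
}

#' Write a mono float32 WAV file
#'
#' @param w A [waveform()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  n <- length(w$samples)
  data_size <- n * 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")   # IEEE float
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(round(w$rate)), con, size = 4, endian = "little")
  writeBin(as.integer(round(w$rate) * 4L), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")   # block align
  writeBin(32L, con, size = 2, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  writeBin(w$samples, con, size = 4, endian = "little")
  invisible(path)
}
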