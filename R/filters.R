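# FIR filtering primitives shared by the envelope and synthesis modules.
# All filters are linear-phase FIRs applied forward-only with the group
# delay compensated by shifting, so event (onset) times stay unbiased.

# 2-3-5-smooth FFT length at or above n
good_fft_length <- function(n) stats::nextn(n, c(2, 3, 5))

# Linear convolution via FFT; returns full length n + m - 1
conv_fft <- function(x, h) {
  n <- length(x); m <- length(h)
  nf <- good_fft_length(n + m - 1L)
  X <- fft(c(x, numeric(nf - n)))
  H <- fft(c(h, numeric(nf - m)))
  Re(fft(X * H, inverse = TRUE))[seq_len(n + m - 1L)] / nf
}

# Apply an odd-length linear-phase FIR, compensating the (m-1)/2 delay.
# Output has the same length as the input.
fir_apply <- function(x, h) {
  m <- length(h)
  stopifnot(m %% 2L == 1L)
  d <- (m - 1L) %/% 2L
  y <- conv_fft(x, h)
  y[(d + 1L):(d + length(x))]
}

# Ideal lowpass impulse response (normalized cutoff fc in cycles/sample),
# odd length m, centered.
ideal_lowpass <- function(m, fc) {
  stopifnot(m %% 2L == 1L)
  k <- seq_len(m) - 1L - (m - 1L) %/% 2L
  h <- ifelse(k == 0, 2 * fc, sin(2 * pi * fc * k) / (pi * k))
  h
}

# Kaiser-windowed lowpass with given passband/stopband edges (Hz) and
# stopband attenuation (dB). Returns the filter taps (odd length).
kaiser_lowpass <- function(rate, pass_hz, stop_hz, atten_db = 60) {
  stopifnot(stop_hz > pass_hz, stop_hz <= rate / 2)
  dw <- 2 * pi * (stop_hz - pass_hz) / rate
  beta <- if (atten_db > 50) {
    0.1102 * (atten_db - 8.7)
  } else if (atten_db >= 21) {
    0.5842 * (atten_db - 21)^0.4 + 0.07886 * (atten_db - 21)
  } else 0
  m <- ceiling((atten_db - 7.95) / (2.285 * dw)) + 1
  if (m %% 2 == 0) m <- m + 1
  m <- as.integer(max(m, 11L))
  w <- as.numeric(signal::kaiser(m, beta))
  h <- ideal_lowpass(m, ((pass_hz + stop_hz) / 2) / rate) * w
  h / sum(h)  # unit DC gain
}

# Kaiser-windowed bandpass with explicit order and beta (matching the
# settings used for vocalization carrier bands: beta = 5.6, order = 640).
kaiser_bandpass <- function(rate, f_low, f_high, order = 640, beta = 5.6) {
  if (f_low <= 0 || f_high <= f_low || f_high >= rate / 2) {
    abort("Bandpass edges must satisfy 0 < f_low < f_high < rate/2.")
  }
  m <- as.integer(order) + 1L
  if (m %% 2L == 0L) m <- m + 1L
  w <- as.numeric(signal::kaiser(m, beta))
  h <- (ideal_lowpass(m, f_high / rate) - ideal_lowpass(m, f_low / rate)) * w
  # normalize to unit gain at band center
  fc <- (f_low + f_high) / 2
  k <- seq_len(m) - 1L
  g <- abs(sum(h * exp(-2i * pi * fc / rate * k)))
  h / g
}

# Magnitude response of an FIR at the given frequencies (Hz)
fir_response <- function(h, rate, freqs) {
  k <- seq_along(h) - 1L
  vapply(freqs, function(f) abs(sum(h * exp(-2i * pi * f / rate * k))),
         numeric(1))
}

# Analytic-signal magnitude via the frequency-domain Hilbert construction.
# Computed on a padded 2-3-5-smooth length; padding only perturbs the ends.
hilbert_envelope_vec <- function(x) {
  n <- length(x)
  nf <- good_fft_length(n)
  X <- fft(c(x, numeric(nf - n)))
  hmul <- numeric(nf)
  if (nf %% 2L == 0L) {
    hmul[1L] <- 1; hmul[nf / 2 + 1L] <- 1
    hmul[2L:(nf / 2)] <- 2
  } else {
    hmul[1L] <- 1
    hmul[2L:((nf + 1L) / 2)] <- 2
  }
  Mod(fft(X * hmul, inverse = TRUE) / nf)[seq_len(n)]
}

# 5-th order B-spline lowpass kernel: five-fold convolution of a boxcar.
# The boxcar width is chosen so the -3 dB point of the composite response
# sits at `cutoff`. For a width of tau seconds the composite response is
# sinc^5(pi f tau); solving sinc(x0) = 2^(-1/10) gives the half-power
# abscissa x0, and tau = x0 / (pi * cutoff).
bspline_kernel <- function(rate, cutoff) {
  x0 <- stats::uniroot(function(x) sin(x) / x - 2^(-1 / 10),
                       c(1e-6, pi / 2), tol = 1e-12)$root
  tau <- x0 / (pi * cutoff)
  m <- max(3L, as.integer(round(tau * rate)))
  if (m %% 2L == 0L) m <- m + 1L
  box <- rep(1 / m, m)
  h <- box
  for (i in 1:4) h <- convolve(h, rev(box), type = "open")
  h / sum(h)
}
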