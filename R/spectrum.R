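#' Slepian (DPSS) tapers
#'
#' Computes the first `k` discrete prolate spheroidal sequences of length
#' `n` with time-bandwidth product `nw`, each normalized to unit energy.
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product (e.g. 7/2).
#' @param k Number of tapers (default `2 * nw - 1`).
#' @return An `n` x `k` matrix, taper order 0 in column 1.
#' @export
dpss_tapers <- function(n, nw = 7 / 2, k = max(1L, floor(2 * nw - 1))) {
  .dpss_cpp(as.integer(n), as.numeric(nw), as.integer(k))
}

new_amps_spectrum <- function(freq, power, rate, nfft, nw = NA_real_,
                              n_tapers = NA_integer_, n_blocks = NA_integer_,
                              kind = "multitaper") {
  out <- tibble(freq = freq, power = power)
  class(out) <- c("amps_spectrum", class(out))
  attr(out, "rate") <- rate
  attr(out, "nfft") <- nfft
  attr(out, "nw") <- nw
  attr(out, "n_tapers") <- n_tapers
  attr(out, "n_blocks") <- n_blocks
  attr(out, "kind") <- kind
  out
}

#' Multitaper amplitude modulation power spectrum (AMPS)
#'
#' One-sided multitaper PSD estimate of an envelope: the envelope is split
#' into non-overlapping blocks of `nfft` samples (zero-padded if shorter
#' than one block), each block is multiplied by `2 nw - 1` Slepian tapers,
#' and tapered periodograms are averaged across tapers and blocks. The
#' envelope mean is removed first: the pulse-train envelope has a large
#' mean whose spectral line at DC would otherwise leak into the lowest
#' frequency bins and mask the flat low-frequency regime.
#'
#' @param e An [envelope_signal()] (or any `waveform`-like object).
#' @param nfft Block/transform length (default 16384; use 262144 to resolve
#'   dense harmonic structure, e.g. periodic pulse trains).
#' @param nw Time-bandwidth product (default 7/2, giving 6 tapers).
#' @param demean Remove the envelope mean before the PSD (default `TRUE`).
#' @return An `amps_spectrum` tibble with columns `freq` (Hz) and `power`
#'   (envelope units^2 / Hz, one-sided).
#' @export
multitaper_amps <- function(e, nfft = 16384, nw = 7 / 2, demean = TRUE) {
  stopifnot(inherits(e, c("envelope", "waveform")))
  x <- e$samples
  rate <- e$rate
  if (demean) x <- x - mean(x)
  n <- length(x)
  if (n < 16L) abort("Envelope too short for a spectral estimate.")
  L <- min(n, nfft)
  k <- max(1L, floor(2 * nw - 1))
  tapers <- dpss_tapers(L, nw, k)
  n_blocks <- max(1L, n %/% L)
  half <- nfft %/% 2 + 1L
  acc <- numeric(half)
  for (b in seq_len(n_blocks)) {
    xb <- x[((b - 1L) * L + 1L):(b * L)]
    for (j in seq_len(k)) {
      xt <- xb * tapers[, j]
      if (L < nfft) xt <- c(xt, numeric(nfft - L))
      X <- fft(xt)[seq_len(half)]
      acc <- acc + Re(X * Conj(X))
    }
  }
  psd <- acc / (rate * n_blocks * k)
  # one-sided scaling (DC and Nyquist appear once)
  psd[2:(half - 1L)] <- 2 * psd[2:(half - 1L)]
  freq <- (seq_len(half) - 1L) * rate / nfft
  new_amps_spectrum(freq, psd, rate = rate, nfft = nfft, nw = nw,
                    n_tapers = k, n_blocks = n_blocks)
}

# interpolate spectrum power (dB) on log-spaced frequencies within `range`
log_sampled_db <- function(s, range, n_points = 200) {
  f <- s$freq
  ok <- f > 0 & s$power > 0
  f_lo <- max(range[1], min(f[ok]))
  f_hi <- min(range[2], max(f[ok]))
  if (f_hi <= f_lo) abort("Frequency range does not overlap the spectrum.")
  fg <- exp(seq(log(f_lo), log(f_hi), length.out = n_points))
  db <- approx(log(f[ok]), 10 * log10(s$power[ok]), xout = log(fg),
               rule = 2)$y
  list(freq = fg, db = db)
}

#' Fit the first-order lowpass spectrum model `C / (f^2 + f_c^2)`
#'
#' Least-squares fit in the dB domain on log-spaced frequency samples
#' (log spacing gives the flat and 1/f^2 regimes comparable weight). For a
#' given cutoff the optimal gain is closed-form, so the fit reduces to a
#' one-dimensional search over `log10(f_c)`, done on a dense multi-start
#' grid spanning 0.01-1000 Hz followed by local refinement.
#'
#' @param s An `amps_spectrum`.
#' @param fit_range Frequency range for the fit, Hz (default 0.1-100; must
#'   span at least a decade).
#' @param n_points Number of log-spaced samples.
#' @return A `lowpass_fit` object with fields `C` (power x Hz^2), `cutoff`
#'   (Hz), `fit_range`, `rms_residual_db`, and `in_range` (`FALSE` flags a
#'   cutoff estimated outside the fitted range, e.g. for a flat spectrum).
#' @export
fit_lowpass <- function(s, fit_range = c(0.1, 100), n_points = 200) {
  if (fit_range[2] / fit_range[1] < 10) {
    abort("`fit_range` must span at least a decade.")
  }
  g <- log_sampled_db(s, fit_range, n_points)
  obj <- function(lfc) {
    fc2 <- (10^lfc)^2
    mdl <- -10 * log10(g$freq^2 + fc2)
    off <- mean(g$db - mdl)
    sum((g$db - mdl - off)^2)
  }
  grid <- seq(-2, 3, by = 0.02)
  vals <- vapply(grid, obj, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(obj, c(lo, hi), tol = 1e-8)
  fc <- 10^opt$minimum
  mdl <- -10 * log10(g$freq^2 + fc^2)
  off <- mean(g$db - mdl)
  res <- g$db - mdl - off
  structure(list(C = 10^(off / 10), cutoff = fc, fit_range = fit_range,
                 rms_residual_db = sqrt(mean(res^2)),
                 in_range = fc >= fit_range[1] && fc <= fit_range[2],
                 n_points = n_points),
            class = "lowpass_fit")
}

#' @export
print.lowpass_fit <- function(x, ...) {
  cat(sprintf(
    "<lowpass fit: f_c = %.4g Hz%s, C = %.4g, rms residual %.2f dB>\n",
    x$cutoff, if (x$in_range) "" else " (outside fit range)",
    x$C, x$rms_residual_db))
  invisible(x)
}

#' Fit the high-frequency power-law scaling exponent
#'
#' Ordinary least squares of `log10 power` against `log10 f` on log-spaced
#' samples; the scaling exponent is `alpha = -slope` (so a 1/f^2 spectrum
#' gives `alpha = 2`).
#'
#' @param s An `amps_spectrum`.
#' @param fit_range Frequency range, Hz (choose it above the cutoff region).
#' @param n_points Number of log-spaced samples.
#' @return A `scaling_fit` with fields `exponent`, `stderr`, `fit_range`.
#' @export
fit_scaling_exponent <- function(s, fit_range = c(20, 200), n_points = 100) {
  n_bins <- sum(s$freq >= fit_range[1] & s$freq <= fit_range[2] &
                  s$power > 0)
  if (n_bins < 10) {
    abort("Fewer than 10 usable frequency bins in `fit_range`.")
  }
  g <- log_sampled_db(s, fit_range, n_points)
  fit <- stats::lm(y ~ x, data = data.frame(x = log10(g$freq),
                                            y = g$db / 10))
  cf <- summary(fit)$coefficients
  structure(list(exponent = -unname(cf["x", "Estimate"]),
                 stderr = unname(cf["x", "Std. Error"]),
                 fit_range = fit_range, n_points = n_points),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling fit: alpha = %.3f (se %.3f) over %g-%g Hz>\n",
              x$exponent, x$stderr, x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' RMS dB error between two spectra
#'
#' Root-mean-square difference of `10 log10` power between two spectra,
#' evaluated on log-spaced frequencies over `range` (defaults to 1-100 Hz,
#' the band used to compare data and model modulation spectra).
#'
#' @param s1,s2 `amps_spectrum` objects (grids may differ; both are
#'   interpolated).
#' @param range Frequency range, Hz.
#' @param n_points Number of log-spaced samples.
#' @return RMS error in dB.
#' @export
rms_db_error <- function(s1, s2, range = c(1, 100), n_points = 200) {
  g1 <- log_sampled_db(s1, range, n_points)
  g2 <- log_sampled_db(s2, range, n_points)
  sqrt(mean((g1$db - g2$db)^2))
}

#' Constant-Q modulation filterbank summary of a spectrum
#'
#' Integrates spectral power in logarithmically spaced bands of width
#' `f/Q`, emulating modulation filters whose bandwidth scales with center
#' frequency. For a `1/f^2` power density the band power falls as `1/f`;
#' for a flat density it grows as `f`; for a dual-regime lowpass it peaks
#' near the cutoff.
#'
#' @param s An `amps_spectrum`.
#' @param Q Quality factor (center frequency / bandwidth), default 1.
#' @param bands_per_octave Band-center spacing.
#' @param f_range Optional center-frequency range, Hz.
#' @return An `amps_spectrum`-classed tibble of band centers (`freq`) and
#'   integrated band power (`power`, envelope units^2).
#' @export
filterbank_amps <- function(s, Q = 1, bands_per_octave = 4, f_range = NULL) {
  if (Q <= 0) abort("`Q` must be positive.")
  f <- s$freq; p <- s$power
  pos <- f > 0
  half_rel <- 1 / (2 * Q)
  if (is.null(f_range)) {
    f_range <- c(min(f[pos]) / (1 - half_rel) * 1.001,
                 max(f) / (1 + half_rel) * 0.999)
  }
  centers <- 2^(seq(log2(f_range[1]), log2(f_range[2]),
                    by = 1 / bands_per_octave))
  bp <- vapply(centers, function(fc) {
    lo <- fc * (1 - half_rel); hi <- fc * (1 + half_rel)
    # trapezoid integral of the density over [lo, hi]
    fg <- sort(unique(c(lo, f[f > lo & f < hi], hi)))
    pg <- approx(f, p, xout = fg, rule = 2)$y
    sum(diff(fg) * (pg[-1] + pg[-length(fg)]) / 2)
  }, numeric(1))
  new_amps_spectrum(centers, bp, rate = attr(s, "rate"),
                    nfft = attr(s, "nfft"), kind = "filterbank")
}

#' Locate spectral peaks and the harmonic fundamental
#'
#' Finds local maxima of the power spectrum at or above `f_min` that rise
#' to within `db_window` dB of the strongest such maximum. For a periodic
#' pulse train the lowest qualifying peak is the harmonic fundamental
#' (equal to the reciprocal of the repetition interval).
#'
#' @param s An `amps_spectrum`.
#' @param f_min Ignore frequencies below this, Hz (excludes DC leakage).
#' @param db_window Keep peaks within this many dB of the strongest peak.
#' @return A tibble of peaks (`freq`, `power`), sorted by frequency.
#' @export
spectrum_peaks <- function(s, f_min = 0.05, db_window = 10) {
  keep <- s$freq >= f_min
  f <- s$freq[keep]; p <- s$power[keep]
  n <- length(p)
  if (n < 3L) abort("Spectrum too short for peak picking.")
  is_pk <- c(FALSE, p[2:(n - 1)] > p[1:(n - 2)] &
                    p[2:(n - 1)] >= p[3:n], FALSE)
  pk <- which(is_pk)
  if (length(pk) == 0L) return(tibble(freq = numeric(), power = numeric()))
  top <- max(p[pk])
  pk <- pk[10 * log10(p[pk]) >= 10 * log10(top) - db_window]
  tibble(freq = f[pk], power = p[pk])
}

#' @rdname spectrum_peaks
#' @export
harmonic_fundamental <- function(s, f_min = 0.05, db_window = 10) {
  pk <- spectrum_peaks(s, f_min = f_min, db_window = db_window)
  if (nrow(pk) == 0L) abort("No qualifying spectral peaks found.")
  min(pk$freq)
}

#' Write a spectrum as CSV (freq_hz, power_db)
#' @param s An `amps_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(s, path) {
  utils::write.csv(
    data.frame(freq_hz = s$freq,
               power_db = ifelse(s$power > 0, 10 * log10(s$power), NA)),
    path, row.names = FALSE)
  invisible(path)
}
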