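#' Render the piecewise-constant model envelope of a pulse sequence
#'
#' Evaluates `x(t) = sum_n A_n rect((t - t_n)/D_n)` on a sample grid: pulse
#' `n` covers the samples whose times fall in `[t_n, t_n + D_n)`. A
#' zero-duration pulse is rendered as a single impulse sample of height
#' `A_n`.
#'
#' @param seq A [pulse_seq()].
#' @param rate Sample rate of the output grid, Hz.
#' @param n_samples Optional output length; defaults to
#'   `round(total_duration * rate)`.
#' @return An [envelope_signal()].
#' @export
render_model_envelope <- function(seq, rate, n_samples = NULL) {
  stopifnot(inherits(seq, "pulse_seq"), rate > 0)
  if (is.null(n_samples)) {
    n_samples <- as.integer(round(attr(seq, "total_duration") * rate))
  }
  x <- numeric(n_samples)
  if (nrow(seq) > 0L) {
    i0 <- ceiling(seq$onset * rate - 1e-9) + 1L
    i1 <- floor((seq$onset + seq$duration) * rate - 1e-9) + 1L
    for (k in seq_len(nrow(seq))) {
      a <- max(i0[k], 1L); b <- min(i1[k], n_samples)
      if (b < a) {           # zero (or sub-sample) duration: one impulse
        a <- min(max(i0[k], 1L), n_samples)
        x[a] <- x[a] + seq$amplitude[k]
      } else {
        x[a:b] <- x[a:b] + seq$amplitude[k]
      }
    }
  }
  envelope_signal(x, rate)
}

# Least-squares scan for the best (start, length) support on a window.
# For support [a, a+d) the conditionally optimal height is the mean of the
# envelope over the support, and SSE = sum(x^2) - S1^2/d with S1 the sum
# over the support. Maximizing S1^2/d (with S1 > 0) minimizes SSE.
# Returns list(a, d, score); ties broken toward smaller d then smaller a
# by strict-improvement scanning in (d ascending, a ascending) order.
scan_support <- function(cs, starts, durs, w) {
  best <- list(a = 1L, d = 1L, score = -Inf)
  for (d in sort(durs)) {
    a_ok <- starts[starts + d - 1L <= w]
    if (length(a_ok) == 0L) next
    s1 <- cs[a_ok + d] - cs[a_ok]
    sc <- ifelse(s1 > 0, s1 * s1 / d, -Inf)
    j <- which.max(sc)   # first maximum: earliest start wins ties
    thr <- if (is.finite(best$score)) {
      best$score + 1e-10 * max(1, abs(best$score))
    } else -Inf
    if (is.finite(sc[j]) && sc[j] > thr) {
      best <- list(a = a_ok[j], d = d, score = sc[j])
    }
  }
  best
}

#' Fit one rectangular pulse to the analysis envelope within a segment
#'
#' Minimizes the squared error between the 250 Hz analysis envelope and a
#' single rectangular pulse `A rect((t - t0)/D)` over the segment extended
#' by `pad` on each side. The search is a coarse grid over (start, duration)
#' on the envelope sample grid with the closed-form optimal amplitude (the
#' envelope mean over the pulse support), followed by an exhaustive local
#' refinement at one-sample resolution. On SSE plateaus ties break toward
#' the smallest duration, then the earliest start.
#'
#' @param e250 The analysis [envelope_signal()].
#' @param segment A one-row segment (list or tibble row with `start_index`,
#'   `end_index`), as produced by [detect_segments()].
#' @param pad Window padding on each side, s.
#' @return A one-row tibble: `onset`, `duration`, `amplitude`, `sse`,
#'   `window_start`, `window_end` (seconds / envelope units).
#' @export
fit_pulse <- function(e250, segment, pad = 0.1) {
  stopifnot(inherits(e250, "envelope"))
  rate <- e250$rate
  n <- length(e250$samples)
  pad_n <- as.integer(round(pad * rate))
  i0 <- max(1L, as.integer(segment$start_index) - pad_n)
  i1 <- min(n, as.integer(segment$end_index) + pad_n)
  w <- i1 - i0 + 1L
  if (w <= 2L) abort("Degenerate segment: fewer than 3 envelope samples.")
  x <- e250$samples[i0:i1]
  cs <- c(0, cumsum(x))
  # coarse grids: at most ~160 candidate starts and durations
  step_a <- max(1L, w %/% 160L)
  step_d <- max(1L, w %/% 160L)
  starts <- seq(1L, w, by = step_a)
  durs <- unique(as.integer(seq(1L, w, by = step_d)))
  best <- scan_support(cs, starts, durs, w)
  # exhaustive refinement around the coarse optimum
  a_lo <- max(1L, best$a - step_a); a_hi <- min(w, best$a + step_a)
  d_lo <- max(1L, best$d - step_d); d_hi <- min(w, best$d + step_d)
  best <- scan_support(cs, a_lo:a_hi, d_lo:d_hi, w)
  sse <- sum(x^2) - best$score
  amp <- (cs[best$a + best$d] - cs[best$a]) / best$d
  onset <- (i0 + best$a - 2L) / rate
  tibble(onset = onset, duration = best$d / rate, amplitude = amp,
         sse = max(sse, 0), window_start = (i0 - 1L) / rate,
         window_end = (i1 - 1L) / rate)
}

#' Fit rectangular pulses to all detected segments
#'
#' @param e250 The analysis [envelope_signal()].
#' @param segments Segment tibble from [detect_segments()].
#' @param pad Window padding per segment, s.
#' @return A tibble with one row per segment (columns as [fit_pulse()]).
#' @export
fit_pulses <- function(e250, segments, pad = 0.1) {
  if (nrow(segments) == 0L) {
    return(tibble(onset = numeric(), duration = numeric(),
                  amplitude = numeric(), sse = numeric(),
                  window_start = numeric(), window_end = numeric()))
  }
  purrr::map_dfr(seq_len(nrow(segments)), function(k) {
    fit_pulse(e250, segments[k, ], pad = pad)
  })
}

#' Assemble fitted pulses into a pulse sequence
#'
#' Sorts fits by onset and resolves any overlap between consecutive fitted
#' pulses by truncating both at the midpoint of the overlapping stretch, so
#' the result satisfies the non-overlap invariant of [pulse_seq()].
#'
#' @param fits Tibble of fits from [fit_pulses()].
#' @param total_duration Recording length T, s (sets the rate `N/T`).
#' @return A [pulse_seq()].
#' @export
assemble_sequence <- function(fits, total_duration) {
  if (nrow(fits) == 0L) return(pulse_seq(total_duration = total_duration))
  fits <- fits[order(fits$onset), ]
  onset <- fits$onset
  end <- fits$onset + fits$duration
  for (k in seq_len(nrow(fits) - 1L)) {
    if (end[k] > onset[k + 1L]) {
      # truncate both at the midpoint of the overlap; if one pulse engulfs
      # the next, the boundary clamps to the shorter pulse's end
      b <- min((onset[k + 1L] + end[k]) / 2, end[k + 1L])
      end[k] <- b
      onset[k + 1L] <- b
    }
  }
  pulse_seq(onset, pmax(end - onset, 0), fits$amplitude, total_duration)
}

#' Write a pulse table to CSV
#' @param seq A [pulse_seq()] or fit tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pulses_csv <- function(seq, path) {
  utils::write.csv(as.data.frame(seq), path, row.names = FALSE)
  invisible(path)
}
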