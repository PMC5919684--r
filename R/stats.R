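#' Joint correlations between pulse amplitudes, durations and intervals
#'
#' Pearson correlations between amplitude and duration (`r_AD`), amplitude
#' and the following inter-onset interval (`r_AI`), and duration and the
#' following interval (`r_DI`), with bootstrap standard errors and a
#' two-sided t-test on the bootstrap distribution at the 1% level. The
#' interval paired with vocalization `n` is `t_{n+1} - t_n` (the interval
#' it opens); set `pairing = "leading"` to pair with the preceding interval
#' instead.
#'
#' @param seq A [pulse_seq()] with at least 10 pulses.
#' @param n_boot Number of bootstrap resamples (0 gives point estimates
#'   only).
#' @param seed Optional integer seed for the bootstrap.
#' @param pairing `"trailing"` (default) or `"leading"`.
#' @param alpha Significance level (default 0.01).
#' @return A tibble with one row per pair: `pair`, `r`, `se`, `p`,
#'   `significant`, `n`.
#' @export
joint_correlations <- function(seq, n_boot = 1000, seed = NULL,
                               pairing = c("trailing", "leading"),
                               alpha = 0.01) {
  stopifnot(inherits(seq, "pulse_seq"))
  pairing <- match.arg(pairing)
  if (nrow(seq) < 10L) abort("Need at least 10 pulses.")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(seq)
  ivl <- diff(seq$onset)
  idx <- if (pairing == "trailing") seq_len(n - 1L) else 2:n
  pairs <- list(
    AD = cbind(seq$amplitude, seq$duration),
    AI = cbind(seq$amplitude[idx], ivl),
    DI = cbind(seq$duration[idx], ivl))
  purrr::map_dfr(names(pairs), function(nm) {
    m <- pairs[[nm]]
    if (sd(m[, 1]) == 0 || sd(m[, 2]) == 0) {
      return(tibble(pair = nm, r = NA_real_, se = NA_real_, p = NA_real_,
                    significant = NA, n = nrow(m)))
    }
    r <- cor(m[, 1], m[, 2])
    if (n_boot > 0) {
      boots <- vapply(seq_len(n_boot), function(b) {
        j <- sample.int(nrow(m), replace = TRUE)
        suppressWarnings(cor(m[j, 1], m[j, 2]))
      }, numeric(1))
      boots <- boots[is.finite(boots)]
      se <- sd(boots)
      p <- 2 * stats::pnorm(-abs(r / se))
      tibble(pair = nm, r = r, se = se, p = p,
             significant = p < alpha, n = nrow(m))
    } else {
      tibble(pair = nm, r = r, se = NA_real_, p = NA_real_,
             significant = NA, n = nrow(m))
    }
  })
}

#' Serial autocorrelation of a parameter series
#'
#' Mean-removed, variance-normalized autocorrelation by lag index
#' (lag 0 is exactly 1). Used to check that fitted durations and
#' amplitudes are serially uncorrelated.
#'
#' @param x Numeric series (e.g. the fitted durations in sequence order).
#' @param max_lag Largest lag, in samples.
#' @param series_name Optional label stored in the result.
#' @return A tibble: `lag`, `autocorr`, `series`.
#' @export
serial_autocorr <- function(x, max_lag = 20L, series_name = "series") {
  if (length(x) <= max_lag) abort("Series shorter than `max_lag`.")
  if (sd(x) == 0) abort("Constant series: autocorrelation undefined.")
  a <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)
  tibble(lag = as.integer(a$lag[, 1, 1]), autocorr = a$acf[, 1, 1],
         series = series_name)
}

#' Autocorrelation of the onset point process
#'
#' Bins the vocalization onset times at `bin_width`, then computes the
#' normalized autocorrelation of the binned counts. An impulse at lag 0
#' with a flat remainder indicates a renewal (serially uncorrelated)
#' process; periodic onsets produce peaks at multiples of the period.
#'
#' @param onsets Numeric vector of onset times, s (or a [pulse_seq()]).
#' @param bin_width Bin width, s (default 0.05).
#' @param max_lag Largest lag, s.
#' @return A tibble: `lag_s`, `autocorr`.
#' @export
point_process_autocorr <- function(onsets, bin_width = 0.05, max_lag = 5) {
  if (inherits(onsets, "pulse_seq")) onsets <- onsets$onset
  if (length(onsets) < 2L) {
    return(tibble(lag_s = 0, autocorr = 1))
  }
  if (length(onsets) < 10L) warn("Fewer than 10 onsets; estimate is noisy.")
  if (bin_width > median(diff(sort(onsets)))) {
    warn("`bin_width` exceeds the median inter-onset interval.")
  }
  t_max <- max(onsets) + bin_width
  counts <- tabulate(pmin(floor(onsets / bin_width) + 1L,
                          ceiling(t_max / bin_width)),
                     nbins = ceiling(t_max / bin_width))
  k <- min(as.integer(round(max_lag / bin_width)), length(counts) - 1L)
  a <- stats::acf(counts, lag.max = k, plot = FALSE, demean = TRUE)
  tibble(lag_s = as.numeric(a$lag[, 1, 1]) * bin_width,
         autocorr = a$acf[, 1, 1])
}

#' Inter-vocalization interval histogram and shifted-exponential summary
#'
#' Histograms the inter-onset intervals, estimates the refractory dead
#' time as the smallest observed interval, and fits the exponential tail
#' rate by maximum likelihood on the intervals above the dead time
#' (`rate = 1 / mean(interval - dead_time)`).
#'
#' @param seq A [pulse_seq()] (or a numeric vector of intervals).
#' @param bin_width Histogram bin width, s.
#' @return A list with `histogram` (tibble `bin_mid`, `count`),
#'   `dead_time_estimate` (s) and `tail_rate` (/s).
#' @export
interval_histogram <- function(seq, bin_width = 0.05) {
  ivl <- if (inherits(seq, "pulse_seq")) diff(seq$onset) else as.numeric(seq)
  if (length(ivl) == 0L) abort("No intervals available.")
  if (length(ivl) < 10L) warn("Fewer than 10 intervals; estimates are noisy.")
  dead <- min(ivl)
  breaks <- seq(0, max(ivl) + bin_width, by = bin_width)
  h <- graphics::hist(ivl, breaks = breaks, plot = FALSE)
  tail_rate <- if (mean(ivl - dead) > 0) 1 / mean(ivl - dead) else NA_real_
  list(histogram = tibble(bin_mid = h$mids, count = h$counts),
       dead_time_estimate = dead, tail_rate = tail_rate)
}
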