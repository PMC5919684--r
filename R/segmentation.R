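#' Estimate background-noise envelope statistics
#'
#' Mean and standard deviation of the envelope over a user-chosen window
#' known to contain only background noise (by default ~2.7 s long). The
#' segmentation threshold is referenced to these statistics, which makes
#' detection invariant to global amplitude scaling of the recording.
#'
#' @param e An [envelope_signal()] (use the 30 Hz segmentation envelope).
#' @param window Numeric `c(t0, t1)` in seconds.
#' @return A tibble: `mean`, `sd`, `segment_duration`.
#' @export
estimate_noise <- function(e, window) {
  stopifnot(inherits(e, "envelope"), length(window) == 2L)
  rate <- e$rate
  i0 <- max(1L, as.integer(floor(window[1] * rate)) + 1L)
  i1 <- min(length(e$samples), as.integer(ceiling(window[2] * rate)))
  if (i1 > length(e$samples) || window[1] < 0 || i0 > length(e$samples)) {
    abort("Noise window lies outside the envelope.")
  }
  if (i1 - i0 + 1L < 10L) {
    abort("Noise window shorter than 10 envelope samples.")
  }
  x <- e$samples[i0:i1]
  tibble(mean = mean(x), sd = sd(x),
         segment_duration = (i1 - i0 + 1L) / rate)
}

#' Detect vocalization segments in the 30 Hz envelope
#'
#' A vocalization is a maximal run of the segmentation envelope above
#' `noise_mean + threshold_sd * noise_sd`, extended outward to the
#' surrounding crossings of a secondary boundary level
#' `noise_mean + boundary_sd * noise_sd` (so each kept segment contains
#' both an onset and an offset and the fitted pulse covers the full
#' excursion). Runs separated by less than `min_gap` are merged and runs
#' shorter than `min_duration` are dropped.
#'
#' @param e30 The 30 Hz segmentation [envelope_signal()].
#' @param noise Noise statistics from [estimate_noise()].
#' @param threshold_sd Detection threshold T_x in noise SDs above the noise
#'   mean (30 for most groups; 10 for rat and speech).
#' @param boundary_sd Secondary boundary level in noise SDs (default 2).
#' @param min_gap Minimum silent gap between segments, s (closer runs are
#'   merged). The default 20 ms suppresses ripple-induced splits while
#'   staying below vocal refractory gaps (~30-150 ms), so genuinely
#'   distinct calls are not merged even after the ~±half-kernel widening
#'   introduced by the 30 Hz smoothing.
#' @param min_duration Minimum segment duration, s.
#' @return A tibble of non-overlapping sorted segments: `start_index`,
#'   `end_index` (1-based, inclusive), `start_s`, `end_s`.
#' @export
detect_segments <- function(e30, noise, threshold_sd = 30, boundary_sd = 2,
                            min_gap = 0.02, min_duration = 0.005) {
  stopifnot(inherits(e30, "envelope"))
  if (threshold_sd <= 0) abort("`threshold_sd` must be positive.")
  if (noise$sd <= 0) abort("Noise SD must be positive (constant envelope?).")
  x <- e30$samples
  rate <- e30$rate
  thr <- noise$mean + threshold_sd * noise$sd
  bnd <- noise$mean + boundary_sd * noise$sd
  empty <- tibble(start_index = integer(), end_index = integer(),
                  start_s = numeric(), end_s = numeric())
  above <- x > thr
  if (!any(above)) return(empty)
  d <- diff(c(FALSE, above, FALSE))
  run_start <- which(d == 1L)
  run_end <- which(d == -1L) - 1L
  # walk outward to the boundary-level crossings (vectorized via cummax)
  n <- length(x)
  below_bnd <- x <= bnd
  idx <- seq_len(n)
  prev_below <- cummax(ifelse(below_bnd, idx, 0L))           # <= i
  next_below <- n + 1L - rev(cummax(rev(ifelse(below_bnd, n + 1L - idx, 0L))))
  next_below[next_below > n] <- n + 1L                        # none after
  ps <- ifelse(run_start > 1L, prev_below[pmax(run_start - 1L, 1L)], 0L)
  run_start <- as.integer(pmax(ps + 1L, 1L))
  ne <- ifelse(run_end < n, next_below[pmin(run_end + 1L, n)], n + 1L)
  ne[ne == 0L] <- n + 1L
  run_end <- as.integer(pmin(ne - 1L, n))
  # boundary extension can make runs touch or nest: merge overlaps
  keep_s <- run_start[1L]; keep_e <- run_end[1L]
  if (length(run_start) > 1L) {
    ss <- run_start[1L]; ee <- run_end[1L]
    out_s <- integer(); out_e <- integer()
    for (k in 2:length(run_start)) {
      if (run_start[k] <= ee + as.integer(round(min_gap * rate))) {
        ee <- max(ee, run_end[k])
      } else {
        out_s <- c(out_s, ss); out_e <- c(out_e, ee)
        ss <- run_start[k]; ee <- run_end[k]
      }
    }
    keep_s <- c(out_s, ss); keep_e <- c(out_e, ee)
  }
  dur <- (keep_e - keep_s + 1L) / rate
  ok <- dur >= min_duration
  tibble(start_index = keep_s[ok], end_index = keep_e[ok],
         start_s = (keep_s[ok] - 1L) / rate, end_s = (keep_e[ok] - 1L) / rate)
}

#' Export segments as CSV or a tab-separated label track
#' @param segments Segment tibble from [detect_segments()].
#' @param path Output path.
#' @param format `"csv"` or `"labels"` (tab-separated start, end, label).
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path, format = c("csv", "labels")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(segments[, c("start_s", "end_s")], path,
                     row.names = FALSE)
  } else {
    utils::write.table(
      data.frame(segments$start_s, segments$end_s,
                 sprintf("voc%03d", seq_len(nrow(segments)))),
      path, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
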