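#' Plot an amplitude modulation power spectrum
#'
#' Log-log AMPS in dB, optionally with the fitted first-order lowpass
#' and/or a reference 1/f^2 line.
#'
#' @param object An `amps_spectrum`.
#' @param lowpass Optional `lowpass_fit` to overlay.
#' @param f2_line Overlay a 1/f^2 reference line anchored at the spectrum's
#'   high-frequency end.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.amps_spectrum <- function(object, lowpass = NULL, f2_line = FALSE,
                                   ...) {
  df <- dplyr::filter(as_tibble(object), .data$freq > 0, .data$power > 0)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$freq,
                                        10 * log10(.data$power))) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "modulation frequency (Hz)", y = "power (dB)")
  if (!is.null(lowpass)) {
    fit_df <- tibble(
      freq = df$freq,
      db = 10 * log10(lowpass$C / (df$freq^2 + lowpass$cutoff^2)))
    p <- p + ggplot2::geom_line(data = fit_df,
                                ggplot2::aes(.data$freq, .data$db),
                                color = "red", linetype = 2)
  }
  if (isTRUE(f2_line)) {
    f_hi <- max(df$freq)
    anchor <- df$power[which.max(df$freq)]
    ref <- tibble(freq = df$freq,
                  db = 10 * log10(anchor * f_hi^2 / df$freq^2))
    p <- p + ggplot2::geom_line(data = ref,
                                ggplot2::aes(.data$freq, .data$db),
                                color = "blue", linetype = 3)
  }
  p
}

#' Plot a pulse sequence as rectangles
#'
#' @param object A [pulse_seq()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pulse_seq <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$onset,
                                    xmax = .data$onset + .data$duration,
                                    ymin = 0, ymax = .data$amplitude),
                       fill = "forestgreen", alpha = 0.7) +
    ggplot2::labs(x = "time (s)", y = "amplitude")
}

#' Plot an envelope with optional fitted pulses and segments
#'
#' @param e An [envelope_signal()].
#' @param seq Optional [pulse_seq()] overlay.
#' @param segments Optional segment tibble overlay.
#' @param max_points Downsample for plotting beyond this many points.
#' @return A ggplot object.
#' @export
plot_envelope <- function(e, seq = NULL, segments = NULL,
                          max_points = 20000) {
  df <- as_tibble(e)
  if (nrow(df) > max_points) {
    df <- df[unique(round(seq(1L, nrow(df), length.out = max_points))), ]
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "envelope")
  if (!is.null(segments) && nrow(segments) > 0) {
    p <- p + ggplot2::geom_rect(
      data = segments,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.15)
  }
  if (!is.null(seq) && nrow(seq) > 0) {
    p <- p + ggplot2::geom_rect(
      data = as_tibble(seq),
      ggplot2::aes(xmin = .data$onset, xmax = .data$onset + .data$duration,
                   ymin = 0, ymax = .data$amplitude),
      inherit.aes = FALSE, color = "forestgreen", fill = NA)
  }
  p
}
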