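#' Tidy a lowpass spectrum fit
#' @param x A `lowpass_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.lowpass_fit <- function(x, ...) {
  tibble(term = c("C", "cutoff"), estimate = c(x$C, x$cutoff))
}

#' @rdname tidy.lowpass_fit
#' @export
glance.lowpass_fit <- function(x, ...) {
  tibble(cutoff = x$cutoff, C = x$C, rms_residual_db = x$rms_residual_db,
         in_range = x$in_range, f_lo = x$fit_range[1], f_hi = x$fit_range[2])
}

#' Tidy a scaling-exponent fit
#' @param x A `scaling_fit`.
#' @param ... Unused.
#' @return A tibble with the exponent estimate and its standard error.
#' @export
tidy.scaling_fit <- function(x, ...) {
  tibble(term = "exponent", estimate = x$exponent, std.error = x$stderr)
}

#' @rdname tidy.scaling_fit
#' @export
glance.scaling_fit <- function(x, ...) {
  tibble(exponent = x$exponent, std.error = x$stderr,
         f_lo = x$fit_range[1], f_hi = x$fit_range[2])
}
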