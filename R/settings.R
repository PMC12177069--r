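#' Create a stimulation setting
#'
#' A stimulation setting is one point in the three-dimensional DBS
#' programming space: pulse amplitude (mA), pulse frequency (Hz) and pulse
#' width (microseconds), plus a flag marking the clinically optimized
#' setting chosen by the treating neurologist.
#'
#' @param amplitude_mA Pulse amplitude in milliamperes.
#' @param frequency_Hz Pulse frequency in hertz.
#' @param pulse_width_us Pulse width in microseconds.
#' @param clinical Logical; `TRUE` for the clinically optimized setting.
#' @return A `stim_setting` object (named numeric coordinates + flag).
#' @examples
#' stim_setting(5.5, 150, 90, clinical = TRUE)
#' @export
stim_setting <- function(amplitude_mA, frequency_Hz, pulse_width_us,
                         clinical = FALSE) {
  stopifnot_scalar_number(amplitude_mA, "amplitude_mA")
  stopifnot_scalar_number(frequency_Hz, "frequency_Hz")
  stopifnot_scalar_number(pulse_width_us, "pulse_width_us")
  structure(
    list(
      amplitude_mA = amplitude_mA,
      frequency_Hz = frequency_Hz,
      pulse_width_us = pulse_width_us,
      clinical = isTRUE(clinical)
    ),
    class = "stim_setting"
  )
}

#' @export
print.stim_setting <- function(x, ...) {
  cat(sprintf(
    "<stim_setting> %.2f mA, %.0f Hz, %.0f us%s\n",
    x$amplitude_mA, x$frequency_Hz, x$pulse_width_us,
    if (x$clinical) " [clinical]" else ""
  ))
  invisible(x)
}

setting_vec <- function(s) {
  c(s$amplitude_mA, s$frequency_Hz, s$pulse_width_us)
}

# safe_range: list(amplitude_mA = c(lo, hi), frequency_Hz = ..., pulse_width_us = ...)
setting_in_box <- function(s, safe_range, tol = 1e-9) {
  v <- setting_vec(s)
  lo <- vapply(safe_range, `[`, numeric(1), 1L)
  hi <- vapply(safe_range, `[`, numeric(1), 2L)
  all(v >= lo - tol & v <= hi + tol)
}

check_safe_range <- function(safe_range) {
  nm <- c("amplitude_mA", "frequency_Hz", "pulse_width_us")
  if (!all(nm %in% names(safe_range))) {
    stop("safe_range must name amplitude_mA, frequency_Hz, pulse_width_us",
         call. = FALSE)
  }
  for (p in nm) {
    r <- safe_range[[p]]
    if (length(r) != 2L || !all(is.finite(r)) || diff(r) <= 0) {
      stop(sprintf("safe_range$%s is degenerate (need lo < hi)", p),
           call. = FALSE)
    }
  }
  invisible(safe_range[nm])
}
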