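#' Build a ground-truth walking-performance response surface
#'
#' The unknown patient-specific mapping from stimulation settings to
#' walking performance is emulated by a smooth unimodal Gaussian bump over
#' the subject's safe parameter box. The optimum location, peak and
#' baseline WPI, per-axis widths and the trial-level observation noise are
#' drawn from seeded distributions and recorded as ground truth for every
#' downstream validation.
#'
#' @param subject A [subject_config()].
#' @param seed Integer seed; the same (subject, seed) pair always yields
#'   the identical surface.
#' @param observation_noise_sd Trial-level WPI noise SD (unitless).
#' @return A `gt_surface` object with fields `optimum` (stim_setting),
#'   `peak_wpi`, `baseline_wpi`, `axis_widths`, `observation_noise_sd`,
#'   `safe_range`.
#' @export
build_surface <- function(subject, seed, observation_noise_sd = 0.03) {
  safe_range <- check_safe_range(subject$safe_range)
  if (observation_noise_sd < 0) stop("observation_noise_sd must be >= 0")
  with_seed(derive_seed(seed, paste0("surface:", subject$subject_id)), function() {
    lo <- vapply(safe_range, `[`, numeric(1), 1L)
    hi <- vapply(safe_range, `[`, numeric(1), 2L)
    span <- hi - lo
    # optimum kept inside the middle 80% of the box
    opt <- lo + span * runif(3, 0.1, 0.9)
    # broad responses: gait effects of DBS parameters vary smoothly over
    # tens of Hz / tenths of mA rather than as sharp resonances
    widths <- span * runif(3, 0.4, 0.8)
    # WPI expressed on the baseline-normalized scale (clinical setting ~ 1):
    # observed per-subject WPI ranges span roughly 0.27-0.47 at the low end
    # and 1.32-1.56 at the high end across tested settings
    peak <- runif(1, 1.30, 1.55)
    baseline <- runif(1, 0.35, 0.50)
    structure(
      list(
        optimum = stim_setting(opt[1], opt[2], opt[3]),
        peak_wpi = peak,
        baseline_wpi = baseline,
        axis_widths = stats::setNames(widths, names(safe_range)),
        observation_noise_sd = observation_noise_sd,
        safe_range = safe_range
      ),
      class = "gt_surface"
    )
  })
}

#' Noise-free surface value at a stimulation setting
#'
#' @param surface A `gt_surface` from [build_surface()].
#' @param setting A [stim_setting()] inside the surface's safe box.
#' @return Expected (noise-free) WPI, in `[baseline_wpi, peak_wpi]`.
#' @export
true_wpi <- function(surface, setting) {
  if (!inherits(surface, "gt_surface")) stop("surface must be a gt_surface")
  if (!setting_in_box(setting, surface$safe_range)) {
    stop("setting lies outside the surface's safe box")
  }
  d <- (setting_vec(setting) - setting_vec(surface$optimum)) /
    unname(surface$axis_widths)
  surface$baseline_wpi +
    (surface$peak_wpi - surface$baseline_wpi) * exp(-0.5 * sum(d^2))
}

#' @export
print.gt_surface <- function(x, ...) {
  o <- setting_vec(x$optimum)
  cat(sprintf(
    "<gt_surface> optimum (%.2f mA, %.1f Hz, %.1f us), peak %.3f, baseline %.3f\n",
    o[1], o[2], o[3], x$peak_wpi, x$baseline_wpi
  ))
  invisible(x)
}

# Regular grid over a safe box: data.frame with the three parameter columns.
setting_grid <- function(safe_range, resolution = c(0.1, 5, 10)) {
  safe_range <- check_safe_range(safe_range)
  axes <- lapply(seq_along(safe_range), function(i) {
    r <- safe_range[[i]]
    g <- seq(r[1], r[2], by = resolution[i])
    if (g[length(g)] < r[2] - 1e-9) g <- c(g, r[2])
    g
  })
  # pulse width varies fastest and amplitude slowest so that row order is
  # lexicographic in (amplitude, frequency, pulse width): which.max then
  # breaks ties toward lower amplitude, then lower frequency.
  g <- expand.grid(pulse_width_us = axes[[3]], frequency_Hz = axes[[2]],
                   amplitude_mA = axes[[1]], KEEP.OUT.ATTRS = FALSE)
  g[, c("amplitude_mA", "frequency_Hz", "pulse_width_us")]
}
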