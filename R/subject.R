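#' Configure a synthetic subject
#'
#' Describes one simulated DBS patient: implanted hemispheres, the safe
#' programming box defined by the treating neurologist, the clinically
#' optimized setting, stride timing, and the gait-phase-locked neural
#' biomarker slopes the generator should realize.
#'
#' `biomarker_slopes` is a named list keyed `"<site>.<band>.<phase>"`
#' (e.g. `"GP.beta.DS2"`). Each value is the target group-level regression
#' coefficient of WPI on that z-scored feature (WPI units per z unit); the
#' generator calibrates its band-power envelopes so a WPI-on-feature
#' regression across the cohort recovers approximately that coefficient.
#'
#' @param subject_id Character id.
#' @param hemispheres 1 (unilateral) or 2 (bilateral implant).
#' @param safe_range Named list with `amplitude_mA`, `frequency_Hz`,
#'   `pulse_width_us`, each `c(lo, hi)`.
#' @param clinical_setting A [stim_setting()] inside `safe_range`.
#' @param stride_period_s Mean stride period (s).
#' @param stride_period_cv Fractional dispersion of the stride period.
#' @param biomarker_slopes Named list of target WPI-on-feature slopes.
#' @param neural_rate_Hz Neural sampling rate; the implanted device streams
#'   at 500 Hz.
#' @param device_accel_rate_Hz On-board accelerometer rate; 64 Hz.
#' @param wearable_rate_Hz Wearable kinematic sampling rate (default 100 Hz).
#' @param clock_offset_s Device-minus-wearable clock offset (s).
#' @return A `subject_config` list.
#' @export
subject_config <- function(subject_id,
                           hemispheres = 2L,
                           safe_range = list(
                             amplitude_mA = c(4.1, 5.5),
                             frequency_Hz = c(60, 190),
                             pulse_width_us = c(70, 90)
                           ),
                           clinical_setting = stim_setting(5.5, 150, 90,
                                                           clinical = TRUE),
                           stride_period_s = 1.1,
                           stride_period_cv = 0.04,
                           biomarker_slopes = default_biomarker_slopes(),
                           neural_rate_Hz = 500,
                           device_accel_rate_Hz = 64,
                           wearable_rate_Hz = 100,
                           clock_offset_s = 0) {
  safe_range <- check_safe_range(safe_range)
  if (!hemispheres %in% c(1L, 2L)) stop("hemispheres must be 1 or 2")
  if (neural_rate_Hz != 500) {
    stop("neural_rate_Hz is fixed at 500 Hz by the streaming device")
  }
  if (device_accel_rate_Hz != 64) {
    stop("device_accel_rate_Hz is fixed at 64 Hz by the streaming device")
  }
  if (stride_period_s <= 0) stop("stride_period_s must be > 0")
  if (!setting_in_box(clinical_setting, safe_range)) {
    stop("clinical_setting lies outside safe_range")
  }
  structure(
    list(
      subject_id = as.character(subject_id),
      hemispheres = as.integer(hemispheres),
      safe_range = safe_range,
      clinical_setting = clinical_setting,
      stride_period_s = stride_period_s,
      stride_period_cv = stride_period_cv,
      biomarker_slopes = biomarker_slopes,
      neural_rate_Hz = neural_rate_Hz,
      device_accel_rate_Hz = device_accel_rate_Hz,
      wearable_rate_Hz = wearable_rate_Hz,
      clock_offset_s = clock_offset_s
    ),
    class = "subject_config"
  )
}

#' Default gait-phase biomarker slopes
#'
#' Pallidal beta power during the double-support phase after the
#' contralateral swing (DS2) and during the ipsilateral swing (ILS)
#' declines as walking performance rises; the default group-level
#' coefficients are -0.22 and -0.23 WPI units per z unit. All other
#' site/band/phase combinations default to zero.
#'
#' @return Named list of slopes.
#' @export
default_biomarker_slopes <- function() {
  list(GP.beta.DS2 = -0.22, GP.beta.ILS = -0.23)
}

#' Example three-subject cohort configuration
#'
#' Mirrors the implant pattern of a three-patient pallidal DBS cohort: two
#' bilateral implants and one unilateral, with subject-specific safe
#' amplitude ranges (4.1-5.5, 2.8-5.0 and 3.5-4.9 mA), tested frequency
#' spans reaching 60-190 Hz, and per-subject clinical settings.
#'
#' @return List of three [subject_config()] objects.
#' @export
example_subjects <- function() {
  list(
    subject_config(
      "S1", hemispheres = 2L,
      safe_range = list(amplitude_mA = c(4.1, 5.5),
                        frequency_Hz = c(60, 190),
                        pulse_width_us = c(70, 90)),
      clinical_setting = stim_setting(5.5, 150, 90, clinical = TRUE)
    ),
    subject_config(
      "S2", hemispheres = 2L,
      safe_range = list(amplitude_mA = c(2.8, 5.0),
                        frequency_Hz = c(60, 180),
                        pulse_width_us = c(60, 70)),
      clinical_setting = stim_setting(4.0, 130, 60, clinical = TRUE)
    ),
    subject_config(
      "S3", hemispheres = 1L,
      safe_range = list(amplitude_mA = c(3.5, 4.9),
                        frequency_Hz = c(60, 190),
                        pulse_width_us = c(60, 80)),
      clinical_setting = stim_setting(3.9, 145, 60, clinical = TRUE)
    )
  )
}
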