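#' Inject artifacts into a trial's neural channels
#'
#' Adds the named contaminant classes to neural channels and records
#' their ground-truth intervals:
#' \describe{
#'   \item{stim_tone}{Stationary sinusoid at the stimulation frequency
#'     plus a half-frequency subharmonic, as produced by some DBS
#'     settings.}
#'   \item{gamma_burst}{Short high-amplitude bursts in the 75-150 Hz
#'     range, scaled to a requested z level relative to the channel's
#'     band-passed SD.}
#'   \item{ekg_spikes}{A periodic (~1.1 Hz) cardiac-like spike train;
#'     injected but deliberately not removed by the preprocessing
#'     pipeline, so its default amplitude sits below the gamma flagging
#'     threshold.}
#'   \item{packet_loss}{Runs of frozen samples emulating dropped
#'     telemetry packets.}
#' }
#'
#' @param recording A `trial_recording`.
#' @param artifact_spec Named list; recognized entries `stim_tone`
#'   (`frequency_Hz`, `amplitude`, `subharmonic_frac`), `gamma_burst`
#'   (`z`, `n`, `duration_s`), `ekg_spikes` (`rate_Hz`, `amplitude`),
#'   `packet_loss` (`n`, `duration_s`). An empty list returns the
#'   recording unchanged (empty ground-truth artifact list).
#' @param seed Integer seed for artifact placement.
#' @param hemisphere Which hemisphere's channels to contaminate.
#' @param channels Channel names to contaminate (default `"GP"`).
#' @return The modified `trial_recording` with ground-truth artifact
#'   intervals appended.
#' @export
inject_artifacts <- function(recording, artifact_spec, seed = 1,
                             hemisphere = "left", channels = "GP") {
  if (is.null(recording$neural)) stop("recording has no neural channels")
  known <- c("stim_tone", "gamma_burst", "ekg_spikes", "packet_loss")
  bad <- setdiff(names(artifact_spec), known)
  if (length(bad)) stop("unknown artifact classes: ",
                        paste(bad, collapse = ", "))
  if (length(artifact_spec) == 0L) return(recording)
  hemi <- recording$neural[[hemisphere]]
  if (is.null(hemi)) stop("hemisphere not present: ", hemisphere)
  fs <- recording$neural_rate_Hz
  n <- length(hemi$time_s)
  dur <- n / fs
  gt <- recording$ground_truth$artifacts
  with_seed(derive_seed(seed, "artifacts"), function() {
    for (ch in channels) {
      x <- hemi[[ch]]
      if (is.null(x)) stop("channel not present: ", ch)
      tt <- hemi$time_s

      sp <- artifact_spec$stim_tone
      if (!is.null(sp)) {
        f0 <- sp$frequency_Hz
        amp <- if (is.null(sp$amplitude)) 0.5 else sp$amplitude
        subf <- if (is.null(sp$subharmonic_frac)) 0.5 else sp$subharmonic_frac
        if (f0 >= fs / 2) stop("stim tone above Nyquist")
        x <- x + amp * sin(2 * pi * f0 * tt) +
          amp * subf * sin(2 * pi * f0 / 2 * tt)
        gt <<- rbind(gt, data.frame(start = 0, end = dur, channel = ch,
                                    kind = "stim_tone"))
      }

      sp <- artifact_spec$gamma_burst
      if (!is.null(sp)) {
        z <- sp$z
        nb <- if (is.null(sp$n)) 5L else sp$n
        bd <- if (is.null(sp$duration_s)) 0.1 else sp$duration_s
        sd0 <- stats::sd(bandpass(x, fs, 75, 150), na.rm = TRUE)
        if (z < 4) {
          warning("gamma burst amplitude below detectability floor; ",
                  "injected anyway")
        }
        starts <- sort(runif(nb, 1, dur - bd - 1))
        # keep bursts apart so ground-truth intervals stay distinct
        for (i in seq_len(nb)) {
          if (i > 1 && starts[i] < starts[i - 1] + bd + 0.5) {
            starts[i] <- starts[i - 1] + bd + 0.5
          }
        }
        # the bursts themselves inflate the band SD that defines the z
        # scale; scale the amplitude so the stated z is realized in the
        # contaminated recording
        n_burst <- round(bd * fs)
        win_ref <- 0.5 - 0.5 * cos(2 * pi * seq_len(n_burst) / n_burst)
        q <- nb * sum(win_ref^2) * 0.5 / length(x)
        denom <- max(1 - z^2 * q, 0.05)
        amp <- z * sd0 / sqrt(denom)
        for (s0 in starts) {
          idx <- which(tt >= s0 & tt < s0 + bd)
          win <- 0.5 - 0.5 * cos(2 * pi * seq_along(idx) / length(idx))
          x[idx] <- x[idx] + amp * win * sin(2 * pi * 110 * tt[idx])
          gt <<- rbind(gt, data.frame(start = s0, end = s0 + bd,
                                      channel = ch, kind = "gamma_burst"))
        }
      }

      sp <- artifact_spec$ekg_spikes
      if (!is.null(sp)) {
        rate <- if (is.null(sp$rate_Hz)) 1.1 else sp$rate_Hz
        amp <- if (is.null(sp$amplitude)) 0.4 else sp$amplitude
        beats <- seq(runif(1, 0, 1 / rate), dur, by = 1 / rate)
        for (b in beats) {
          idx <- which(tt >= b & tt < b + 0.04)
          if (!length(idx)) next
          ph <- (tt[idx] - b) / 0.04
          x[idx] <- x[idx] + amp * sin(pi * ph) * sign(cos(pi * ph))
        }
        gt <<- rbind(gt, data.frame(start = 0, end = dur, channel = ch,
                                    kind = "ekg_spikes"))
      }

      sp <- artifact_spec$packet_loss
      if (!is.null(sp)) {
        np <- if (is.null(sp$n)) 1L else sp$n
        pd <- if (is.null(sp$duration_s)) 0.12 else sp$duration_s
        starts <- sort(runif(np, 1, dur - pd - 1))
        for (i in seq_len(np)) {
          if (i > 1 && starts[i] < starts[i - 1] + pd + 0.5) {
            starts[i] <- starts[i - 1] + pd + 0.5
          }
        }
        for (s0 in starts) {
          idx <- which(tt >= s0 & tt < s0 + pd)
          x[idx] <- x[idx[1]]
          gt <<- rbind(gt, data.frame(start = s0, end = s0 + pd,
                                      channel = ch, kind = "packet_loss"))
        }
      }

      hemi[[ch]] <- x
    }
    recording$neural[[hemisphere]] <- hemi
    recording$ground_truth$artifacts <- gt
    recording
  })
}
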