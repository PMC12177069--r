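#' Simulate one overground walking trial
#'
#' Generates a fully seeded trial: ground-truth gait events with
#' stride-to-stride jitter whose dispersion falls as walking performance
#' rises; footswitch pulses, goniometer angles, pelvis and wrist
#' trajectories that invert the WPI component definitions so that the
#' aggregated trial metrics recover the trial's true WPI; neural channels
#' (pallidal + two cortical bipolar pairs per hemisphere at 500 Hz) as
#' 1/f background plus gait-phase-gated band oscillations realizing the
#' subject's biomarker slopes; and a chest/device accelerometer pair
#' sharing heel-strike acceleration anchors separated by the configured
#' clock offset.
#'
#' The walker covers a short back-and-forth loop: every `turn_every`-th
#' stride is a turning stride during which the pelvis heading reverses;
#' turn strides are flagged in the ground truth.
#'
#' @param subject A [subject_config()].
#' @param surface A [build_surface()] ground-truth surface.
#' @param setting A [stim_setting()] inside the subject's safe box.
#' @param n_strides Number of complete gait cycles per reference side
#'   (a "step" is a half-stride, so 200 steps = 100 strides); must be >= 4.
#' @param seed Integer seed.
#' @param visit_id,trial_id Identifiers stored in the recording.
#' @param turn_every Insert a turning stride every this many strides
#'   (default 5, matching a 6 m loop); `Inf` for straight walking.
#' @param neural Generate neural channels (disable to speed up pure
#'   kinematics simulations).
#' @param phase_targets Optional per-site planned z-score targets for band
#'   power in each gait phase (list `site -> band -> named DS1/CLS/DS2/ILS
#'   vector` or `site -> band -> 4 x n matrix`); computed from the
#'   subject's biomarker slopes when omitted.
#' @param w_obs Optional pre-drawn noisy trial-level WPI (cohort planning
#'   draws it up front so neural calibration and kinematics share one
#'   value); defaults to `true_wpi(setting) + noise`.
#' @return A `trial_recording` object.
#' @export
simulate_trial <- function(subject, surface, setting, n_strides = 20,
                           seed = 1, visit_id = "V1", trial_id = "T1",
                           turn_every = 5, neural = TRUE,
                           phase_targets = NULL, w_obs = NULL) {
  if (n_strides < 4) stop("n_strides must be >= 4 to form usable cycles")
  if (!setting_in_box(setting, subject$safe_range)) {
    stop("setting lies outside the subject's safe box")
  }
  sd_trial <- derive_seed(seed, paste0("trial:", trial_id))
  with_seed(sd_trial, function() {
    T0 <- subject$stride_period_s
    w_true <- true_wpi(surface, setting)
    if (is.null(w_obs)) {
      w_obs <- w_true + rnorm(1, 0, surface$observation_noise_sd)
    }
    w_rel <- (w_obs - surface$baseline_wpi) /
      (surface$peak_wpi - surface$baseline_wpi)
    w_rel <- min(max(w_rel, 0), 1)

    # trial-level kinematic targets; variability falls as performance rises
    targets <- list(
      stride_velocity = 0.5 + 0.9 * w_rel,
      arm_swing = 0.4 + 1.1 * w_rel,
      step_time_cv = 0.11 - 0.07 * w_rel,
      step_length_cv = 0.10 - 0.06 * w_rel
    )

    ev <- gt_event_times(n_strides, T0, targets$step_time_cv)
    turn_idx <- if (is.finite(turn_every) && turn_every <= n_strides) {
      seq(turn_every, n_strides, by = turn_every)
    } else {
      integer(0)
    }

    fs_kin <- subject$wearable_rate_Hz
    t_end <- max(ev$time_s) + 0.5
    tk <- seq(0, t_end, by = 1 / fs_kin)

    streams <- kinematic_streams(tk, ev, n_strides, targets, turn_idx, fs_kin)

    # chest (wearable clock) and device (device clock) accelerometers share
    # heel-strike bump anchors separated by the clock offset
    lhs <- ev$time_s[ev$label == "LHS"]
    amp_pk <- rnorm(length(lhs), 1.5, 0.15)
    chest <- gauss_bump_train(tk, lhs, amp_pk, 0.05) + rnorm(length(tk), 0, 0.02)
    off <- subject$clock_offset_s
    # the device clock may lead or lag the wearable clock; its stream
    # must span all shifted anchor times
    td <- seq(min(0, off) - 0.5, t_end + max(0, off) + 0.5,
              by = 1 / subject$device_accel_rate_Hz)
    dev_acc <- gauss_bump_train(td, lhs + off, amp_pk, 0.05) +
      rnorm(length(td), 0, 0.02)

    neural_out <- NULL
    if (neural) {
      if (is.null(phase_targets)) {
        phase_targets <- standalone_phase_targets(subject, w_rel)
      }
      neural_out <- lapply(seq_len(subject$hemispheres), function(h) {
        neural_channels(
          t_end + max(0, off) + 0.5, subject$neural_rate_Hz,
          ev, off, phase_targets,
          seed = derive_seed(sd_trial, paste0("neural", h))
        )
      })
      names(neural_out) <- c("left", "right")[seq_len(subject$hemispheres)]
    }

    structure(
      list(
        trial_id = trial_id, subject_id = subject$subject_id,
        visit_id = visit_id, setting = setting,
        kin = c(list(time_s = tk), streams,
                list(chest_accel = chest, rate_Hz = fs_kin)),
        device_accel = list(time_s = td, value = dev_acc,
                            rate_Hz = subject$device_accel_rate_Hz),
        neural = neural_out,
        neural_rate_Hz = subject$neural_rate_Hz,
        ground_truth = list(
          events = ev, n_strides = n_strides, turn_strides = turn_idx,
          w_true = w_true, w_obs = w_obs, w_rel = w_rel,
          metric_targets = targets, clock_offset_s = off,
          phase_targets = phase_targets,
          artifacts = data.frame(start = numeric(0), end = numeric(0),
                                 channel = character(0), kind = character(0))
        ),
        seed = seed
      ),
      class = "trial_recording"
    )
  })
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf(
    "<trial_recording> %s/%s/%s: %d strides, wpi_true %.3f%s\n",
    x$subject_id, x$visit_id, x$trial_id, x$ground_truth$n_strides,
    x$ground_truth$w_true, if (is.null(x$neural)) " (no neural)" else ""
  ))
  invisible(x)
}

# Ground-truth event times. Left-referenced cycles LHS -> RTO -> RHS -> LTO
# -> next LHS; one extra RTO/RHS after the final LHS completes the last
# right-referenced cycle, so both sides contain n_strides full cycles.
gt_event_times <- function(n_strides, T0, step_time_cv) {
  sd_step <- step_time_cv * T0 / 2
  n_steps <- 2 * (n_strides + 1)
  steps <- pmax(rnorm(n_steps, T0 / 2, sd_step), 0.3 * T0 / 2)
  t <- 0.5
  lhs <- numeric(n_strides + 1)
  rhs <- numeric(n_strides + 1)
  for (k in seq_len(n_strides + 1)) {
    lhs[k] <- t
    rhs[k] <- t + steps[2 * k - 1]
    t <- rhs[k] + steps[2 * k]
  }
  rto <- lhs + 0.12 * T0 + rnorm(n_strides + 1, 0, 0.004)
  lto <- rhs + 0.12 * T0 + rnorm(n_strides + 1, 0, 0.004)
  lab <- c("LHS", "RTO", "RHS", "LTO")
  ev <- data.frame(
    time_s = c(lhs, rto, rhs, lto[seq_len(n_strides)]),
    label = c(rep("LHS", n_strides + 1), rep("RTO", n_strides + 1),
              rep("RHS", n_strides + 1), rep("LTO", n_strides))
  )
  ev <- ev[order(ev$time_s), ]
  rownames(ev) <- NULL
  ev$label <- factor(ev$label, levels = lab)
  ev
}

# Pelvis, heading, wrists, footswitch and goniometer streams.
kinematic_streams <- function(tk, ev, n_strides, targets, turn_idx, fs_kin) {
  lhs <- ev$time_s[ev$label == "LHS"]
  rhs <- ev$time_s[ev$label == "RHS"]
  rto <- ev$time_s[ev$label == "RTO"]
  lto <- ev$time_s[ev$label == "LTO"]

  # alternating heel strikes with cumulative distance anchors
  hs_t <- sort(c(lhs, rhs))
  n_steps <- length(hs_t) - 1
  sv <- targets$stride_velocity
  ms <- mean(diff(hs_t))
  step_len <- pmax(rnorm(n_steps, sv * ms, targets$step_length_cv * sv * ms),
                   0.05)
  pos_anchor <- c(0, cumsum(step_len))
  pelvis <- approx(hs_t, pos_anchor, xout = tk, rule = 2)$y

  heading <- numeric(length(tk))
  dir_sign <- 1
  for (k in turn_idx) {
    if (k + 1 > length(lhs)) next
    a <- lhs[k]
    b <- lhs[k + 1]
    ramp <- pmin(pmax((tk - a) / (b - a), 0), 1)
    heading <- heading + dir_sign * 180 * ramp
    dir_sign <- -dir_sign
  }

  amp <- pmax(rnorm(n_strides, targets$arm_swing, 0.04), 0.05)
  wrist_l <- numeric(length(tk))
  for (k in seq_len(n_strides)) {
    sel <- tk >= lhs[k] & tk < lhs[k + 1]
    ph <- (tk[sel] - lhs[k]) / (lhs[k + 1] - lhs[k])
    wrist_l[sel] <- 0.5 * amp[k] * sin(2 * pi * ph)
  }
  wrist_r <- -wrist_l

  fsw <- footswitch_streams(tk, lhs, rhs, rto, lto)
  gon <- goniometer_streams(tk, lhs, rhs, rto, lto)

  c(list(pelvis_pos = pelvis, pelvis_heading = heading,
         wrist_l = wrist_l, wrist_r = wrist_r),
    fsw, gon)
}

# Eight force-sensitive-resistor channels (heel, first/fifth metatarsal,
# hallux per foot). Heel channels rise at heel strike; forefoot channels
# stay loaded until the respective toe off, the hallux deactivating last.
footswitch_streams <- function(tk, lhs, rhs, rto, lto) {
  T0 <- mean(diff(lhs))
  pulse <- function(on, off) {
    y <- numeric(length(tk))
    for (i in seq_along(on)) y[tk >= on[i] & tk < off[i]] <- 1
    y
  }
  n_l <- length(lto)
  n_r <- length(rto)
  list(
    fsr_heel_l = pulse(lhs, lhs + 0.35 * T0),
    fsr_met1_l = pulse(lhs[seq_len(n_l)] + 0.08 * T0, lto - 0.02),
    fsr_met5_l = pulse(lhs[seq_len(n_l)] + 0.10 * T0, lto - 0.04),
    fsr_toe_l  = pulse(lhs[seq_len(n_l)] + 0.12 * T0, lto),
    fsr_heel_r = pulse(rhs, rhs + 0.35 * T0),
    fsr_met1_r = pulse(c(0.1, head(rhs, -1) + 0.08 * T0), rto - 0.02),
    fsr_met5_r = pulse(c(0.1, head(rhs, -1) + 0.10 * T0), rto - 0.04),
    fsr_toe_r  = pulse(c(0.1, head(rhs, -1) + 0.12 * T0), rto)
  )
}

# Ankle dorsiflexion angle: a sharp dorsiflexion peak at heel strike and a
# plantarflexion drop whose steepest descent lies at toe off (followed by a
# swing-phase recovery), so heel strikes sit at angle maxima and toe offs at
# minima of angular velocity.
goniometer_streams <- function(tk, lhs, rhs, rto, lto) {
  ankle <- function(hs, to) {
    y <- 10 * gauss_bump_train(tk, hs, rep(1, length(hs)), 0.12)
    for (k in seq_along(to)) {
      y <- y - 8 * pnorm((tk - to[k]) / 0.02) +
        8 * pnorm((tk - to[k] - 0.30) / 0.10)
    }
    y
  }
  list(gonio_l = ankle(lhs, lto), gonio_r = ankle(rhs, rto))
}

gauss_bump_train <- function(t, centers, amps, width) {
  y <- numeric(length(t))
  for (i in seq_along(centers)) {
    sel <- abs(t - centers[i]) < 5 * width
    y[sel] <- y[sel] + amps[i] * exp(-0.5 * ((t[sel] - centers[i]) / width)^2)
  }
  y
}

# --- neural generation ------------------------------------------------------

# Gait phase label per neural sample given ground-truth events (shifted onto
# the device clock by `offset`); 0 = outside any complete cycle.
phase_index_stream <- function(tt, ev, offset) {
  cyc <- build_cycles(ev)
  ph <- integer(length(tt))
  bounds <- c("lhs", "rto", "rhs", "lto", "lhs_next")
  for (i in seq_len(nrow(cyc))) {
    b <- as.numeric(cyc[i, bounds]) + offset
    for (p in 1:4) {
      ph[tt >= b[p] & tt < b[p + 1]] <- p
    }
  }
  ph
}

# Multi-tone band carrier with unit RMS: tones spread across the band so
# every wavelet row inside the band carries signal.
tone_carrier <- function(tt, freqs) {
  y <- numeric(length(tt))
  phs <- runif(length(freqs), 0, 2 * pi)
  for (i in seq_along(freqs)) y <- y + sin(2 * pi * freqs[i] * tt + phs[i])
  y / sqrt(length(freqs) / 2)
}

# 1/f^1 background noise via FFT shaping.
pink_noise <- function(n, sd = 1) {
  nf <- stats::nextn(n, 2)
  w <- rnorm(nf)
  W <- fft(w)
  f <- c(1, seq_len(nf - 1))
  shape <- 1 / sqrt(pmin(f, nf - f + 1))
  x <- Re(fft(W * shape, inverse = TRUE)) / nf
  x <- x[seq_len(n)]
  x * sd / stats::sd(x)
}

BETA_TONES <- c(14, 17, 20, 23, 26)
THETA_TONES <- c(5, 6.5)

# One hemisphere's three bipolar channels. Band-power envelopes are gated on
# gait-phase intervals: per-phase planned relative power 1 + kappa * T with
# T the planned z target, so per-visit z-scoring of wavelet power recovers
# the planned pattern up to noise attenuation.
neural_channels <- function(dur, fs, ev, offset, phase_targets, seed,
                            kappa = 0.45) {
  with_seed(seed, function() {
    n <- ceiling(dur * fs)
    tt <- (seq_len(n) - 1) / fs
    ph <- phase_index_stream(tt, ev, offset)

    env_for <- function(site, band) {
      targ <- phase_targets[[site]][[band]]
      if (is.null(targ)) targ <- c(DS1 = 0, CLS = 0, DS2 = 0, ILS = 0)
      tcl <- pmin(pmax(as.numeric(targ), -2), 2)
      p <- 1 + kappa * tcl
      a <- sqrt(pmax(p, 0.05))
      out <- numeric(n)
      out[ph > 0] <- a[ph[ph > 0]]
      # baseline amplitude outside complete cycles
      out[ph == 0] <- 1
      out
    }

    shared_beta <- tone_carrier(tt, BETA_TONES)
    own_beta_A <- tone_carrier(tt, BETA_TONES + 0.4)
    own_beta_B <- tone_carrier(tt, BETA_TONES - 0.4)
    theta <- tone_carrier(tt, THETA_TONES)

    bg_sd <- 0.18
    gp <- env_for("GP", "beta") * shared_beta +
      0.45 * theta + pink_noise(n, bg_sd)
    ctxA <- env_for("ctxA", "beta") *
      (0.75 * shared_beta + 0.66 * own_beta_A) +
      0.35 * theta + pink_noise(n, bg_sd)
    ctxB <- env_for("ctxB", "beta") *
      (0.5 * shared_beta + 0.87 * own_beta_B) +
      0.35 * theta + pink_noise(n, bg_sd)

    list(time_s = tt, GP = gp, ctxA = ctxA, ctxB = ctxB, rate_Hz = fs)
  })
}

# Planned per-phase z targets for a trial simulated outside a cohort: phase
# contrasts plus the subject's biomarker slopes applied to the standardized
# performance level (nominal cohort WPI SD 0.15).
standalone_phase_targets <- function(subject, w_rel, w_sd_nominal = 0.25) {
  w_std <- (w_rel - 0.5) / w_sd_nominal
  targets_from_slopes(subject$biomarker_slopes, w_std)
}

PHASE_CONSTANTS <- c(DS1 = 0.6, CLS = 0.9, DS2 = -0.4, ILS = -0.6)

# Build site -> band -> phase target vectors from feature slopes. `slope` is
# the target WPI-on-feature regression coefficient; the planned feature
# z-value declines with standardized performance w_std with gain chosen by
# the cohort-level calibration (see calibrate_feature_gain); here the gain
# defaults to slope scaled into z units.
targets_from_slopes <- function(slopes, w_std, gain_scale = 2.0) {
  sites <- c("GP", "ctxA", "ctxB")
  out <- lapply(sites, function(site) {
    tv <- PHASE_CONSTANTS
    for (nm in names(slopes)) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      if (length(parts) == 3 && parts[1] == site && parts[2] == "beta") {
        tv[parts[3]] <- tv[parts[3]] + gain_scale * slopes[[nm]] * w_std
      }
    }
    list(beta = tv)
  })
  names(out) <- sites
  out
}
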