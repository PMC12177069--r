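#' Trial-level gait metrics for every trial of a cohort
#'
#' Runs the kinematic pipeline (footswitch event detection, cycle
#' construction, turn exclusion, stride metrics, trial aggregation) on
#' each trial.
#'
#' @param cohort A [simulate_cohort()] result (or any list of
#'   `trial_recording` under `$trials` with a `$manifest`).
#' @param use_ground_truth_events Use the generator's ground-truth events
#'   instead of detected ones (noise-free closure checks).
#' @return Data frame: `trial_id`, `visit_id`, `subject_id`, the four
#'   WPI metrics, `n_valid_strides`, `usable`.
#' @export
cohort_gait_metrics <- function(cohort, use_ground_truth_events = FALSE) {
  rows <- lapply(cohort$manifest$trial_id, function(tid) {
    tr <- cohort$trials[[tid]]
    sm <- trial_stride_metrics(tr, use_ground_truth_events)
    agg <- aggregate_trial_metrics(sm)
    cbind(data.frame(trial_id = tid, visit_id = tr$visit_id,
                     subject_id = tr$subject_id), agg)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Detected (or ground-truth) cycles and stride metrics for one trial.
trial_stride_metrics <- function(tr, use_ground_truth_events = FALSE) {
  rate <- tr$kin$rate_Hz
  events <- if (use_ground_truth_events) {
    tr$ground_truth$events
  } else {
    detect_events_fsr(tr$kin, rate)
  }
  cyc <- build_cycles(events)
  cyc <- exclude_turns(cyc, tr$kin$pelvis_heading, rate)
  compute_stride_metrics(cyc, tr$kin$pelvis_pos, tr$kin$wrist_l,
                         tr$kin$wrist_r, rate)
}

#' Per-visit WPI scores for a cohort
#'
#' Normalizes each visit's trial metrics, applies the WPI formula,
#' baseline-normalizes against the visit's clinical trial and ranks the
#' trials.
#'
#' @param cohort A cohort.
#' @param metrics Optional precomputed [cohort_gait_metrics()] output.
#' @param use_ground_truth_events Passed through when `metrics` is NULL.
#' @return Data frame `trial_id`, `visit_id`, `subject_id`, `raw`,
#'   `baseline_normalized`, `rank`.
#' @export
cohort_wpi <- function(cohort, metrics = NULL,
                       use_ground_truth_events = FALSE) {
  if (is.null(metrics)) {
    metrics <- cohort_gait_metrics(cohort, use_ground_truth_events)
  }
  man <- cohort$manifest
  out <- list()
  for (vid in unique(man$visit_id)) {
    mv <- metrics[metrics$visit_id == vid & metrics$usable, , drop = FALSE]
    if (nrow(mv) < 2L) next
    comp <- normalize_metrics(mv)
    scores <- data.frame(trial_id = mv$trial_id, visit_id = vid,
                         subject_id = mv$subject_id,
                         raw = compute_wpi(comp))
    clin <- man$trial_id[man$visit_id == vid & man$clinical]
    if (!clin %in% scores$trial_id) next
    scores <- tryCatch(baseline_normalize(scores, clin),
                       error = function(e) {
                         warning("visit ", vid, " unusable: ",
                                 conditionMessage(e), call. = FALSE)
                         NULL
                       })
    if (is.null(scores)) next
    scores <- rank_trials(scores)
    out[[vid]] <- scores
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extract gait-phase-locked spectral features for a cohort
#'
#' The full neural feature pipeline: device/wearable synchronization via
#' acceleration-peak anchors; 1 Hz zero-phase high-pass; gamma-outlier
#' blanking (8 z, 200 ms buffers); packet-loss detection;
#' artifact-based cycle exclusion; Morlet scalograms and wavelet
#' coherence; per-visit per-frequency z-scoring (separately per
#' hemisphere and site/pair); canonical-band averaging; and per-phase
#' averaging over usable non-turn cycles.
#'
#' @param cohort A cohort with neural channels.
#' @param sites Power sites to extract (subset of GP, ctxA, ctxB).
#' @param pairs Coherence pairs (subset of "GP-ctxA", "GP-ctxB",
#'   "ctxA-ctxB"); empty vector to skip coherence.
#' @param bands Band names (see [canonical_bands()]).
#' @param fmin,fmax Analysis frequency range (Hz).
#' @param voices Voices per octave for the wavelet grid.
#' @param use_ground_truth_events Use generator ground-truth events.
#' @return Long data frame: `subject_id`, `hemisphere`, `site_or_pair`,
#'   `kind`, `band`, `phase`, `trial_id`, `visit_id`, `value`.
#' @export
cohort_features <- function(cohort, sites = c("GP", "ctxA", "ctxB"),
                            pairs = c("GP-ctxA", "GP-ctxB", "ctxA-ctxB"),
                            bands = c("delta", "theta", "alpha", "beta"),
                            fmin = 1, fmax = 30, voices = 10,
                            use_ground_truth_events = FALSE) {
  man <- cohort$manifest
  rows <- list()
  for (vid in unique(man$visit_id)) {
    tids <- man$trial_id[man$visit_id == vid]
    prep <- lapply(tids, function(tid) {
      prepare_trial_neural(cohort$trials[[tid]], use_ground_truth_events)
    })
    names(prep) <- tids
    hemis <- names(cohort$trials[[tids[1]]]$neural)
    for (hemi in hemis) {
      cwt_cache <- list()
      get_cwt <- function(tid, site) {
        key <- paste(tid, site)
        if (is.null(cwt_cache[[key]])) {
          cwt_cache[[key]] <<- cwt_complex(prep[[tid]]$clean[[hemi]][[site]],
                                           500, fmin, fmax, voices)
        }
        cwt_cache[[key]]
      }
      keys <- c(as.list(sites), strsplit(pairs, "-", fixed = TRUE))
      for (key in keys) {
        is_pair <- length(key) == 2L
        maps <- lapply(tids, function(tid) {
          if (is_pair) {
            wcoh_core(get_cwt(tid, key[1]), get_cwt(tid, key[2]), 500,
                      voices)
          } else {
            cc <- get_cwt(tid, key)
            if (ncol(cc$W) == 0L) {
              new_tf_map("power", matrix(numeric(0), length(cc$freq_Hz), 0),
                         cc$freq_Hz, 500)
            } else {
              new_tf_map("power", Mod(cc$W)^2, cc$freq_Hz, 500)
            }
          }
        })
        names(maps) <- tids
        nonempty <- vapply(maps, function(m) ncol(m$values) > 0, logical(1))
        if (!any(nonempty)) next
        zmaps <- zscore_per_frequency(maps[nonempty])
        for (tid in tids[nonempty]) {
          cyc <- if (is_pair) {
            a <- prep[[tid]]$cycles[[hemi]][[key[1]]]
            b <- prep[[tid]]$cycles[[hemi]][[key[2]]]
            a[a$cycle_index %in% b$cycle_index, , drop = FALSE]
          } else {
            prep[[tid]]$cycles[[hemi]][[key]]
          }
          if (nrow(cyc) == 0L) next
          for (band in bands) {
            series <- band_average(zmaps[[tid]], band)
            pa <- phase_average(series, 500, cyc)
            rows[[length(rows) + 1L]] <- data.frame(
              subject_id = cohort$trials[[tid]]$subject_id,
              hemisphere = hemi,
              site_or_pair = paste(key, collapse = "-"),
              kind = if (is_pair) "coherence" else "power",
              band = band, phase = GAIT_PHASES,
              trial_id = tid, visit_id = vid,
              value = unname(pa$per_trial)
            )
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Preprocess one trial's neural data: sync, cycles on the device clock,
# per-channel high-pass + blanking, per-channel usable cycles.
prepare_trial_neural <- function(tr, use_ground_truth_events = FALSE) {
  if (is.null(tr$neural)) stop("trial has no neural channels: ", tr$trial_id)
  rate_kin <- tr$kin$rate_Hz
  events <- if (use_ground_truth_events) {
    tr$ground_truth$events
  } else {
    detect_events_fsr(tr$kin, rate_kin)
  }
  cyc <- build_cycles(events)
  cyc <- exclude_turns(cyc, tr$kin$pelvis_heading, rate_kin)
  cyc <- cyc[!cyc$is_turn, , drop = FALSE]
  sync <- estimate_sync(tr$device_accel,
                        list(time_s = tr$kin$time_s,
                             value = tr$kin$chest_accel))
  cyc_dev <- cyc
  for (cl in c("lhs", "rto", "rhs", "lto", "lhs_next")) {
    cyc_dev[[cl]] <- cyc_dev[[cl]] + sync$offset_s
  }
  clean <- list()
  cycles <- list()
  for (hemi in names(tr$neural)) {
    clean[[hemi]] <- list()
    cycles[[hemi]] <- list()
    for (site in c("GP", "ctxA", "ctxB")) {
      x <- tr$neural[[hemi]][[site]]
      if (is.null(x)) next
      gm <- gamma_outlier_mask(x, 500)
      pl <- detect_packet_loss(x, 500)
      hp <- highpass(x, 500, 1)
      clean[[hemi]][[site]] <- apply_blanking(hp, gm)
      cycles[[hemi]][[site]] <- exclude_contaminated_cycles(
        cyc_dev, gm$intervals, pl
      )
    }
  }
  list(sync = sync, cycles = cycles, clean = clean)
}

#' Assemble the long biomarker feature table
#'
#' Joins extracted phase-band features with the cohort manifest and the
#' per-trial WPI scores into the analysis-ready long table (one row per
#' feature per trial).
#'
#' @param features Output of [cohort_features()].
#' @param wpi Output of [cohort_wpi()].
#' @param manifest Cohort manifest.
#' @return Data frame adding `wpi` (baseline-normalized), `amplitude_mA`,
#'   `frequency_Hz`, `pulse_width_us`, `clinical` to the feature rows.
#'   Errors listing orphan trials when features reference trials missing
#'   from the manifest.
#' @export
build_feature_table <- function(features, wpi, manifest) {
  orphans <- setdiff(unique(features$trial_id), manifest$trial_id)
  if (length(orphans)) {
    stop("trials absent from manifest: ", paste(orphans, collapse = ", "))
  }
  mi <- match(features$trial_id, manifest$trial_id)
  wi <- match(features$trial_id, wpi$trial_id)
  out <- cbind(
    features,
    wpi = wpi$baseline_normalized[wi],
    manifest[mi, c("amplitude_mA", "frequency_Hz", "pulse_width_us",
                   "clinical")]
  )
  rownames(out) <- NULL
  out
}

#' Feature-level synthetic phase features
#'
#' Generates per-trial phase-band feature values directly from the
#' statistical model the waveform generator realizes (feature =
#' intercept + slope-calibrated component + noise), bypassing signal
#' synthesis. Used to calibrate and power the statistical estimators at
#' scales where full waveform simulation is unnecessary.
#'
#' @param n_subjects,n_visits,n_trials Cohort shape.
#' @param slope Target WPI-on-feature regression coefficient.
#' @param hemispheres Hemisphere count per subject (recycled).
#' @param wpi_sd Between-trial SD of baseline-normalized WPI.
#' @param feature_noise_sd Trial-level feature noise (z units).
#' @param subject_sd SD of per-subject WPI intercepts.
#' @param seed Integer seed.
#' @return Data frame `subject_id`, `hemisphere`, `trial_id`, `wpi`,
#'   `feature`.
#' @export
simulate_phase_features <- function(n_subjects = 3, n_visits = 4,
                                    n_trials = 3, slope = -0.22,
                                    hemispheres = c(2, 2, 1),
                                    wpi_sd = 0.2, feature_noise_sd = 0.45,
                                    subject_sd = 0.1, seed = 1) {
  with_seed(derive_seed(seed, "phase-features"), function() {
    hemis <- rep_len(hemispheres, n_subjects)
    rows <- list()
    # invert the regression: choose the feature-on-WPI gain c and noise
    # so that regressing WPI on the feature recovers `slope`
    c_gain <- 0.5
    sn2 <- abs(c_gain * wpi_sd / slope) - c_gain^2
    if (sn2 <= 0) sn2 <- feature_noise_sd^2
    for (s in seq_len(n_subjects)) {
      b0 <- rnorm(1, 1, subject_sd)
      for (v in seq_len(n_visits)) {
        for (i in seq_len(n_trials)) {
          w <- b0 + rnorm(1, 0, wpi_sd)
          u <- (w - b0) / wpi_sd
          for (h in seq_len(hemis[s])) {
            feat <- sign(slope) * c_gain * u + rnorm(1, 0, sqrt(sn2))
            rows[[length(rows) + 1L]] <- data.frame(
              subject_id = paste0("S", s),
              hemisphere = c("left", "right")[h],
              trial_id = sprintf("S%d_V%d_T%d_H%d", s, v, i, h),
              wpi = w, feature = feat
            )
          }
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
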