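#' Estimate the device/wearable clock offset from acceleration peaks
#'
#' The implanted stimulator's on-board accelerometer (64 Hz) and the
#' chest-worn wearable accelerometer both see the same heel-strike
#' acceleration transients. Prominent peaks are detected in both streams,
#' converted to impulse trains on a common 64 Hz grid, and the offset
#' (device minus wearable) is the cross-correlation lag that best aligns
#' them, refined by matching individual peak pairs.
#'
#' @param device List with `time_s` and `value` (device accelerometer).
#' @param wearable List with `time_s` and `value` (wearable accelerometer).
#' @param max_offset_s Search range for the offset (default 10 s).
#' @return A `sync_model` list: `offset_s`, `anchors` (matched peak-time
#'   pairs), `residual_sd_s`, `n_anchors`.
#' @export
estimate_sync <- function(device, wearable, max_offset_s = 10) {
  fs <- 64
  pk_d <- accel_peaks(device$value, 1 / mean(diff(device$time_s)))
  pk_w <- accel_peaks(wearable$value, 1 / mean(diff(wearable$time_s)))
  pk_d <- pk_d + device$time_s[1]
  pk_w <- pk_w + wearable$time_s[1]
  if (length(pk_d) < 1L || length(pk_w) < 1L) {
    stop("no acceleration peaks found; trial cannot be synchronized")
  }
  t0 <- min(pk_d, pk_w) - max_offset_s
  t1 <- max(pk_d, pk_w) + max_offset_s
  grid <- seq(t0, t1, by = 1 / fs)
  train <- function(pk) {
    y <- numeric(length(grid))
    y[pmin(pmax(round((pk - t0) * fs) + 1L, 1L), length(grid))] <- 1
    y
  }
  yd <- train(pk_d)
  yw <- train(pk_w)
  lags <- seq(-round(max_offset_s * fs), round(max_offset_s * fs))
  score <- vapply(lags, function(L) {
    if (L >= 0) {
      sum(yd[(1 + L):length(yd)] * yw[1:(length(yw) - L)])
    } else {
      sum(yd[1:(length(yd) + L)] * yw[(1 - L):length(yw)])
    }
  }, numeric(1))
  if (max(score) < 1) {
    stop("acceleration peak trains share no content; cannot synchronize")
  }
  lag0 <- lags[which.max(score)] / fs
  # refine: match each device peak to nearest wearable peak under lag0
  d_match <- vapply(pk_d, function(p) {
    j <- which.min(abs(pk_w + lag0 - p))
    if (abs(pk_w[j] + lag0 - p) <= 2 / fs) pk_w[j] else NA_real_
  }, numeric(1))
  ok <- !is.na(d_match)
  # unrelated streams produce only chance alignments; require that at
  # least half the device peaks find a wearable partner
  if (!any(ok) || mean(ok) < 0.5) {
    stop("acceleration peak trains do not match; cannot synchronize")
  }
  offs <- pk_d[ok] - d_match[ok]
  structure(
    list(offset_s = mean(offs),
         anchors = data.frame(device_s = pk_d[ok], wearable_s = d_match[ok]),
         residual_sd_s = if (sum(ok) > 1) stats::sd(offs) else 0,
         n_anchors = sum(ok)),
    class = "sync_model"
  )
}

# Prominent acceleration peaks: local maxima above mean + 2 SD, separated
# by at least 0.4 s. Returns times relative to stream start.
accel_peaks <- function(x, rate, min_sep_s = 0.4) {
  thr <- mean(x) + 2 * stats::sd(x)
  n <- length(x)
  if (n < 3L) return(numeric(0))
  is_pk <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n],
             FALSE) & x > thr
  idx <- which(is_pk)
  if (length(idx) == 0L) return(numeric(0))
  keep <- idx[1]
  for (i in idx[-1]) {
    if ((i - keep[length(keep)]) / rate >= min_sep_s) {
      keep <- c(keep, i)
    } else if (x[i] > x[keep[length(keep)]]) {
      keep[length(keep)] <- i
    }
  }
  (keep - 1L) / rate
}

#' Peak-anchor amplitude and inter-arrival statistics
#'
#' Summarizes the acceleration peaks used as synchronization anchors:
#' distribution of peak amplitudes and of the intervals between
#' consecutive peaks, per trial and pooled.
#'
#' @param peaks List of data frames with `time_s`, `amplitude` (one per
#'   trial), or a single such data frame.
#' @return List `per_trial` (data frame of per-trial summaries) and
#'   `pooled` (one-row data frame).
#' @export
anchor_stats <- function(peaks) {
  if (is.data.frame(peaks)) peaks <- list(peaks)
  summ <- function(p, id) {
    iat <- diff(sort(p$time_s))
    data.frame(
      trial = id, n_peaks = nrow(p),
      amp_mean = mean(p$amplitude), amp_sd = stats::sd(p$amplitude),
      amp_q25 = unname(quantile(p$amplitude, 0.25)),
      amp_q75 = unname(quantile(p$amplitude, 0.75)),
      iat_mean = if (length(iat)) mean(iat) else NA_real_,
      iat_sd = if (length(iat) > 1) stats::sd(iat) else
        if (length(iat) == 1) 0 else NA_real_
    )
  }
  per <- do.call(rbind, lapply(seq_along(peaks),
                               function(i) summ(peaks[[i]], i)))
  all_p <- do.call(rbind, peaks)
  pooled <- summ(all_p, NA)
  iat_all <- unlist(lapply(peaks, function(p) diff(sort(p$time_s))))
  pooled$iat_mean <- if (length(iat_all)) mean(iat_all) else NA_real_
  pooled$iat_sd <- if (length(iat_all) > 1) stats::sd(iat_all) else NA_real_
  list(per_trial = per, pooled = pooled)
}

#' Zero-phase high-pass filter
#'
#' Butterworth high-pass applied forward and backward (zero phase; the
#' effective order doubles). Missing samples split the signal into
#' contiguous segments that are filtered independently, so gaps are
#' propagated rather than interpolated.
#'
#' @param x Signal vector (may contain NA).
#' @param rate Sampling rate (Hz).
#' @param cutoff_Hz High-pass cutoff; must be below Nyquist.
#' @param order Butterworth order (default 4).
#' @return Filtered signal, NA where the input was NA.
#' @export
highpass <- function(x, rate, cutoff_Hz = 1, order = 4) {
  if (cutoff_Hz >= rate / 2) stop("cutoff must be below the Nyquist rate")
  bf <- signal::butter(order, cutoff_Hz / (rate / 2), type = "high")
  filter_segments(x, function(seg) signal::filtfilt(bf, seg),
                  min_len = 3 * order * 3)
}

bandpass <- function(x, rate, low_Hz, high_Hz, order = 4) {
  if (high_Hz >= rate / 2) stop("band edge must be below the Nyquist rate")
  bf <- signal::butter(order, c(low_Hz, high_Hz) / (rate / 2), type = "pass")
  filter_segments(x, function(seg) signal::filtfilt(bf, seg),
                  min_len = 6 * order * 3)
}

# Apply `fn` to each contiguous non-NA segment; short segments left NA.
filter_segments <- function(x, fn, min_len = 30) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (!r$values[i] || r$lengths[i] < min_len) next
    seg <- starts[i]:ends[i]
    out[seg] <- fn(x[seg])
  }
  out
}

#' Flag high-amplitude gamma-range outliers
#'
#' Multi-step artifact detector for device-streamed field potentials:
#' a Butterworth high-pass at 4 Hz (order 4, detection only) removes
#' low-frequency drift; the result is band-passed to 75-150 Hz; per-sample
#' z-scores are computed over the trial; samples strictly exceeding the
#' 8 z threshold are flagged (a sample at exactly z = 8 is not); each
#' flagged run is dilated by a 200 ms blanking buffer on each side and
#' overlapping runs are merged.
#'
#' @param x Neural signal at `rate` Hz.
#' @param rate Sampling rate (500 Hz for the streaming device).
#' @param z_threshold Flagging threshold in z units (strict inequality).
#' @param buffer_s Blanking buffer on each side of a flagged run.
#' @param detect_highpass_Hz,detect_order Detection high-pass settings.
#' @param gamma_band Detection band (Hz).
#' @return An `artifact_mask`: list with per-sample logical `mask`,
#'   `intervals` (start_s, end_s, provenance), `rate_Hz`, `z` (the
#'   detection z-scores).
#' @export
gamma_outlier_mask <- function(x, rate, z_threshold = 8, buffer_s = 0.2,
                               detect_highpass_Hz = 4, detect_order = 4,
                               gamma_band = c(75, 150)) {
  n <- length(x)
  if (n < rate) {
    warning("trial shorter than 1 s; no artifact detection attempted")
    return(empty_mask(n, rate))
  }
  d <- highpass(x, rate, detect_highpass_Hz, detect_order)
  g <- bandpass(d, rate, gamma_band[1], gamma_band[2])
  mu <- mean(g, na.rm = TRUE)
  sg <- stats::sd(g, na.rm = TRUE)
  z <- (g - mu) / sg
  flagged <- !is.na(z) & abs(z) > z_threshold
  ints <- mask_to_intervals(flagged, rate)
  if (nrow(ints) > 0L) {
    ints$start <- pmax(0, ints$start - buffer_s)
    ints$end <- pmin(n / rate, ints$end + buffer_s)
    ints <- merge_intervals(ints)
  }
  mask <- intervals_to_mask(ints, n, rate)
  structure(
    list(mask = mask,
         intervals = if (nrow(ints)) {
           data.frame(start_s = ints$start, end_s = ints$end,
                      provenance = "gamma_outlier")
         } else {
           data.frame(start_s = numeric(0), end_s = numeric(0),
                      provenance = character(0))
         },
         rate_Hz = rate, z = z),
    class = "artifact_mask"
  )
}

empty_mask <- function(n, rate) {
  structure(
    list(mask = logical(n),
         intervals = data.frame(start_s = numeric(0), end_s = numeric(0),
                                provenance = character(0)),
         rate_Hz = rate, z = rep(NA_real_, n)),
    class = "artifact_mask"
  )
}

#' Blank masked samples
#'
#' Replaces masked samples with NA; all other samples are returned
#' unchanged. Idempotent: applying the same mask twice equals once.
#'
#' @param x Signal vector.
#' @param mask An `artifact_mask` or logical vector of the same length.
#' @return `x` with masked samples set to NA.
#' @export
apply_blanking <- function(x, mask) {
  m <- if (inherits(mask, "artifact_mask")) mask$mask else mask
  if (length(m) != length(x)) stop("mask length does not match signal")
  x[m] <- NA_real_
  x
}

#' Detect packet-loss runs
#'
#' The streaming device occasionally drops telemetry packets, which shows
#' up as runs of exactly repeated (frozen) or zero samples. Runs of at
#' least `min_run_s` are flagged; flagged runs closer than `merge_gap_s`
#' are merged. This frozen/zero-run operationalization is an
#' interpretation of device packet loss; timestamped containers can also
#' carry explicit gaps, which appear here as NA runs and are flagged too.
#'
#' @param x Signal vector.
#' @param rate Sampling rate (Hz).
#' @param min_run_s Minimum flagged run length (default 0.05 s).
#' @param merge_gap_s Runs closer than this merge (default 0.05 s).
#' @return Data frame `start_s`, `end_s`, `provenance = "packet_loss"`.
#' @export
detect_packet_loss <- function(x, rate, min_run_s = 0.05,
                               merge_gap_s = 0.05) {
  frozen <- c(FALSE, diff(x) == 0)
  frozen[is.na(frozen)] <- FALSE
  # a run of k equal consecutive samples yields k-1 TRUEs; extend back one
  frozen <- frozen | c(frozen[-1], FALSE)
  bad <- frozen | x == 0 | is.na(x)
  bad[is.na(bad)] <- TRUE
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= round(min_run_s * rate)
  ints <- data.frame(start = (starts[keep] - 1L) / rate,
                     end = ends[keep] / rate)
  ints <- merge_intervals(ints, gap = merge_gap_s)
  if (nrow(ints) == 0L) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      provenance = character(0)))
  }
  data.frame(start_s = ints$start, end_s = ints$end,
             provenance = "packet_loss")
}

#' Exclude artifact-contaminated gait cycles
#'
#' A cycle is dropped if any packet loss overlaps it at all, or if more
#' than half of any single gait phase is blanked by the gamma-outlier
#' mask. Cycles and masks must already live on a common (device) clock.
#'
#' @param cycles Output of [build_cycles()], on the device clock.
#' @param gamma_intervals Data frame `start_s`, `end_s` of blanked runs
#'   (may be NULL).
#' @param packet_intervals Data frame `start_s`, `end_s` of packet-loss
#'   runs (may be NULL).
#' @param max_phase_blanked Phase blanking fraction above which the cycle
#'   is dropped (default 0.5).
#' @return `cycles` restricted to usable rows; a `dropped` attribute
#'   records cycle indices and reasons.
#' @export
exclude_contaminated_cycles <- function(cycles, gamma_intervals = NULL,
                                        packet_intervals = NULL,
                                        max_phase_blanked = 0.5) {
  std <- function(ints) {
    if (is.null(ints) || nrow(ints) == 0L) {
      return(data.frame(start = numeric(0), end = numeric(0)))
    }
    data.frame(start = ints$start_s, end = ints$end_s)
  }
  gi <- std(gamma_intervals)
  pi_ <- std(packet_intervals)
  drop_idx <- integer(0)
  reason <- character(0)
  bounds <- list(DS1 = c("lhs", "rto"), CLS = c("rto", "rhs"),
                 DS2 = c("rhs", "lto"), ILS = c("lto", "lhs_next"))
  for (i in seq_len(nrow(cycles))) {
    cy <- cycles[i, ]
    if (interval_overlap(cy$lhs, cy$lhs_next, pi_) > 0) {
      drop_idx <- c(drop_idx, i)
      reason <- c(reason, "packet_loss")
      next
    }
    for (ph in names(bounds)) {
      a <- cy[[bounds[[ph]][1]]]
      b <- cy[[bounds[[ph]][2]]]
      if (interval_overlap(a, b, gi) / (b - a) > max_phase_blanked) {
        drop_idx <- c(drop_idx, i)
        reason <- c(reason, paste0("gamma_blanking:", ph))
        break
      }
    }
  }
  keep <- setdiff(seq_len(nrow(cycles)), drop_idx)
  out <- cycles[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- data.frame(
    cycle_index = cycles$cycle_index[drop_idx], reason = reason
  )
  out
}
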