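#' Detect gait events from footswitch (FSR) channels
#'
#' Heel strike is the upward threshold crossing of the heel channel; toe
#' off is the downward crossing of the last-active forefoot channel
#' (pointwise maximum of the hallux and metatarsal channels). The
#' threshold is 10% of each channel's trial maximum, with a 50 ms
#' debounce so contact chatter does not double-trigger.
#'
#' @param fsw Named list (or data.frame) of the eight footswitch channels
#'   `fsr_heel_l`, `fsr_met1_l`, `fsr_met5_l`, `fsr_toe_l` and the right
#'   counterparts.
#' @param rate Sampling rate in Hz.
#' @param threshold_frac Threshold as a fraction of the channel maximum.
#' @param debounce_s Minimum separation between same-type events.
#' @return Data frame `time_s`, `label` (LHS/RTO/RHS/LTO), time-ordered,
#'   with a `quality` attribute listing flat/saturated channels (empty
#'   character vector when all channels were usable).
#' @export
detect_events_fsr <- function(fsw, rate, threshold_frac = 0.10,
                              debounce_s = 0.05) {
  need <- c("fsr_heel_l", "fsr_met1_l", "fsr_met5_l", "fsr_toe_l",
            "fsr_heel_r", "fsr_met1_r", "fsr_met5_r", "fsr_toe_r")
  if (!all(need %in% names(fsw))) {
    stop("footswitch channels missing: ",
         paste(setdiff(need, names(fsw)), collapse = ", "))
  }
  quality <- character(0)
  ev <- list()
  for (side in c("l", "r")) {
    heel <- fsw[[paste0("fsr_heel_", side)]]
    fore <- pmax(fsw[[paste0("fsr_met1_", side)]],
                 fsw[[paste0("fsr_met5_", side)]],
                 fsw[[paste0("fsr_toe_", side)]])
    hs_lab <- if (side == "l") "LHS" else "RHS"
    to_lab <- if (side == "l") "LTO" else "RTO"
    if (max(heel, na.rm = TRUE) - min(heel, na.rm = TRUE) < 1e-9) {
      quality <- c(quality, paste0("fsr_heel_", side))
    } else {
      t_hs <- threshold_crossings(heel, rate, threshold_frac, "up", debounce_s)
      ev[[length(ev) + 1L]] <- data.frame(time_s = t_hs, label = hs_lab)
    }
    if (max(fore, na.rm = TRUE) - min(fore, na.rm = TRUE) < 1e-9) {
      quality <- c(quality, paste0("fsr_forefoot_", side))
    } else {
      t_to <- threshold_crossings(fore, rate, threshold_frac, "down", debounce_s)
      ev[[length(ev) + 1L]] <- data.frame(time_s = t_to, label = to_lab)
    }
  }
  out <- if (length(ev)) do.call(rbind, ev) else {
    data.frame(time_s = numeric(0), label = character(0))
  }
  out <- out[order(out$time_s), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "quality") <- quality
  out
}

threshold_crossings <- function(x, rate, threshold_frac, direction, debounce_s) {
  thr <- min(x, na.rm = TRUE) +
    threshold_frac * (max(x, na.rm = TRUE) - min(x, na.rm = TRUE))
  above <- x >= thr
  idx <- if (direction == "up") {
    which(!head(above, -1) & tail(above, -1)) + 1L
  } else {
    which(head(above, -1) & !tail(above, -1)) + 1L
  }
  tt <- (idx - 1L) / rate
  if (length(tt) > 1L) {
    keep <- c(TRUE, diff(tt) >= debounce_s)
    tt <- tt[keep]
  }
  tt
}

#' Detect gait events from goniometer (ankle angle) signals
#'
#' Fallback detector for trials where footswitch signal strength is poor
#' (e.g. toe walking). Heel strike is approximated by the local maximum of
#' ankle dorsiflexion preceding loading; toe off by the peak
#' plantarflexion velocity (most negative angular velocity). Both are
#' standard kinematic surrogates and are flagged as approximate.
#'
#' @param gonio Named list with `gonio_l` and `gonio_r` ankle angles (deg).
#' @param rate Sampling rate (Hz).
#' @param min_period_s Minimum separation between successive same-side
#'   events (default 0.6 s).
#' @return Data frame `time_s`, `label`, time-ordered; `quality` attribute
#'   as in [detect_events_fsr()].
#' @export
detect_events_goniometer <- function(gonio, rate, min_period_s = 0.6) {
  quality <- character(0)
  ev <- list()
  for (side in c("l", "r")) {
    ang <- gonio[[paste0("gonio_", side)]]
    hs_lab <- if (side == "l") "LHS" else "RHS"
    to_lab <- if (side == "l") "LTO" else "RTO"
    if (is.null(ang) || max(ang) - min(ang) < 1e-9) {
      quality <- c(quality, paste0("gonio_", side))
      next
    }
    pk <- prominent_peaks(ang, rate, min_period_s)
    ev[[length(ev) + 1L]] <- data.frame(time_s = pk, label = hs_lab)
    vel <- c(diff(ang), 0) * rate
    tr <- prominent_peaks(-vel, rate, min_period_s)
    ev[[length(ev) + 1L]] <- data.frame(time_s = tr, label = to_lab)
  }
  out <- if (length(ev)) do.call(rbind, ev) else {
    data.frame(time_s = numeric(0), label = character(0))
  }
  out <- out[order(out$time_s), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "quality") <- quality
  out
}

# Local maxima above half the signal range, separated by min_period_s.
prominent_peaks <- function(x, rate, min_period_s) {
  n <- length(x)
  thr <- min(x) + 0.5 * (max(x) - min(x))
  is_pk <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n],
             FALSE) & x > thr
  idx <- which(is_pk)
  if (length(idx) == 0L) return(numeric(0))
  keep <- idx[1]
  for (i in idx[-1]) {
    if ((i - keep[length(keep)]) / rate >= min_period_s) {
      keep <- c(keep, i)
    } else if (x[i] > x[keep[length(keep)]]) {
      keep[length(keep)] <- i
    }
  }
  (keep - 1L) / rate
}

#' Build phase-segmented gait cycles from events
#'
#' A left-referenced gait cycle runs LHS -> RTO -> RHS -> LTO -> next LHS,
#' defining the half-open phases DS1 (first double support) `[lhs, rto)`,
#' CLS (contralateral swing) `[rto, rhs)`, DS2 (second double support)
#' `[rhs, lto)` and ILS (ipsilateral swing) `[lto, lhs_next)`. Cycles with
#' missing or out-of-order internal events are skipped without affecting
#' their neighbours.
#'
#' @param events Data frame `time_s`, `label`, time-sorted.
#' @param reference_side `"left"` (LHS-anchored, default) or `"right"`
#'   (RHS-anchored with labels mirrored).
#' @return Data frame, one row per complete cycle: `lhs`, `rto`, `rhs`,
#'   `lto`, `lhs_next`, `stride_time_s`, `cycle_index`, `is_turn`
#'   (initialized `FALSE`; see [exclude_turns()]).
#' @export
build_cycles <- function(events, reference_side = c("left", "right")) {
  reference_side <- match.arg(reference_side)
  lab <- as.character(events$label)
  if (reference_side == "right") {
    map <- c(LHS = "RHS", RHS = "LHS", LTO = "RTO", RTO = "LTO")
    lab <- unname(map[lab])
  }
  tt <- events$time_s
  anchors <- which(lab == "LHS")
  rows <- list()
  if (length(anchors) >= 2L) {
    for (a in seq_len(length(anchors) - 1L)) {
      i0 <- anchors[a]
      i1 <- anchors[a + 1L]
      inner <- lab[(i0 + 1L):(i1 - 1L)]
      if (!identical(inner, c("RTO", "RHS", "LTO"))) next
      tt_c <- tt[i0:i1]
      if (any(diff(tt_c) <= 0)) next
      rows[[length(rows) + 1L]] <- data.frame(
        lhs = tt_c[1], rto = tt_c[2], rhs = tt_c[3], lto = tt_c[4],
        lhs_next = tt_c[5], cycle_index = a
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(lhs = numeric(0), rto = numeric(0), rhs = numeric(0),
               lto = numeric(0), lhs_next = numeric(0),
               cycle_index = integer(0))
  }
  out$stride_time_s <- out$lhs_next - out$lhs
  out$is_turn <- rep(FALSE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Flag turning cycles from the pelvis heading stream
#'
#' Cycles whose cumulative heading change exceeds `threshold_deg` are
#' flagged as turns; analysis proceeds on the straight-walking cycles.
#' Flagging never alters the cycle timing of retained strides.
#'
#' @param cycles Output of [build_cycles()].
#' @param heading Pelvis heading stream (degrees).
#' @param rate Heading sampling rate (Hz).
#' @param threshold_deg Cumulative within-cycle heading change marking a
#'   turn (default 45).
#' @return `cycles` with `is_turn` set. With a missing heading stream all
#'   cycles are kept and a warning is issued.
#' @export
exclude_turns <- function(cycles, heading, rate, threshold_deg = 45) {
  if (is.null(heading)) {
    warning("heading stream missing; keeping all cycles")
    return(cycles)
  }
  for (i in seq_len(nrow(cycles))) {
    i0 <- max(1L, floor(cycles$lhs[i] * rate) + 1L)
    i1 <- min(length(heading), ceiling(cycles$lhs_next[i] * rate))
    if (i1 <= i0) next
    dh <- abs(heading[i1] - heading[i0])
    cycles$is_turn[i] <- dh > threshold_deg
  }
  cycles
}
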