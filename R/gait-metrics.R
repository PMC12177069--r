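#' Stride-level spatiotemporal metrics
#'
#' For each non-turn gait cycle computes stride length (pelvis horizontal
#' displacement over the cycle), stride velocity (stride length / stride
#' time), step time (interval between the alternating heel strikes inside
#' the cycle), step length (pelvis anteroposterior displacement between
#' those heel strikes) and arm swing amplitude (mean over both arms of
#' the per-cycle anteroposterior wrist displacement range).
#'
#' @param cycles Output of [build_cycles()] (optionally after
#'   [exclude_turns()]).
#' @param pelvis Pelvis anteroposterior position stream (m).
#' @param wrist_l,wrist_r Wrist anteroposterior position streams (m).
#' @param rate Kinematic sampling rate (Hz).
#' @return Data frame, one row per cycle: `stride_index`, `stride_time_s`,
#'   `stride_length_m`, `stride_velocity`, `step_time_s`, `step_length_m`,
#'   `arm_swing_amplitude`, `is_turn`. Strides with a stream gap (NA)
#'   inside the cycle are dropped.
#' @export
compute_stride_metrics <- function(cycles, pelvis, wrist_l, wrist_r, rate) {
  at <- function(x, t) {
    i <- pmin(pmax(round(t * rate) + 1L, 1L), length(x))
    x[i]
  }
  rows <- list()
  for (i in seq_len(nrow(cycles))) {
    cy <- cycles[i, ]
    i0 <- max(1L, floor(cy$lhs * rate) + 1L)
    i1 <- min(length(pelvis), ceiling(cy$lhs_next * rate))
    seg <- i0:i1
    if (anyNA(pelvis[seg]) || anyNA(wrist_l[seg]) || anyNA(wrist_r[seg])) {
      next
    }
    stride_len <- abs(at(pelvis, cy$lhs_next) - at(pelvis, cy$lhs))
    step_time <- cy$rhs - cy$lhs
    step_len <- abs(at(pelvis, cy$rhs) - at(pelvis, cy$lhs))
    swing <- mean(c(diff(range(wrist_l[seg])), diff(range(wrist_r[seg]))))
    rows[[length(rows) + 1L]] <- data.frame(
      stride_index = cy$cycle_index,
      stride_time_s = cy$stride_time_s,
      stride_length_m = stride_len,
      stride_velocity = stride_len / cy$stride_time_s,
      step_time_s = step_time,
      step_length_m = step_len,
      arm_swing_amplitude = swing,
      is_turn = cy$is_turn
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(stride_index = integer(0), stride_time_s = numeric(0),
               stride_length_m = numeric(0), stride_velocity = numeric(0),
               step_time_s = numeric(0), step_length_m = numeric(0),
               arm_swing_amplitude = numeric(0), is_turn = logical(0))
  }
  rownames(out) <- NULL
  out
}

#' Aggregate stride metrics to trial level
#'
#' Means for stride velocity and arm swing amplitude; coefficient of
#' variation (sample SD / mean, ddof = 1) for step time and step length.
#' Only non-turn strides contribute.
#'
#' @param stride_metrics Output of [compute_stride_metrics()].
#' @param min_strides Minimum usable stride count (default 5); below it
#'   the trial is marked unusable.
#' @return One-row data frame: `stride_velocity`, `arm_swing_amplitude`,
#'   `step_length_cv`, `step_time_cv`, `n_valid_strides`, `usable`.
#' @export
aggregate_trial_metrics <- function(stride_metrics, min_strides = 5) {
  sm <- stride_metrics[!stride_metrics$is_turn, , drop = FALSE]
  n <- nrow(sm)
  if (n < min_strides) {
    return(data.frame(stride_velocity = NA_real_,
                      arm_swing_amplitude = NA_real_,
                      step_length_cv = NA_real_, step_time_cv = NA_real_,
                      n_valid_strides = n, usable = FALSE))
  }
  data.frame(
    stride_velocity = mean(sm$stride_velocity),
    arm_swing_amplitude = mean(sm$arm_swing_amplitude),
    step_length_cv = cv(sm$step_length_m),
    step_time_cv = cv(sm$step_time_s),
    n_valid_strides = n,
    usable = TRUE
  )
}

#' Stride-order consistency within walking bouts
#'
#' Groups strides by their order within each straight-walking bout
#' (bouts are delimited by turn strides) and tests whether stride times
#' differ across within-bout orders with a Kruskal-Wallis test. A
#' significant order effect would indicate that acceleration/deceleration
#' phases contaminate the steady-state gait estimates.
#'
#' @param stride_metrics Output of [compute_stride_metrics()] including
#'   turn flags (turn strides delimit bouts and are excluded).
#' @return List with `summary` (per-order n, mean and SD of stride time)
#'   and `test` (htest or NULL when fewer than 2 orders have >= 2 strides).
#' @export
stride_order_consistency <- function(stride_metrics) {
  sm <- stride_metrics[order(stride_metrics$stride_index), , drop = FALSE]
  bout <- cumsum(sm$is_turn)
  sm <- sm[!sm$is_turn, , drop = FALSE]
  bout <- bout[!stride_metrics$is_turn[order(stride_metrics$stride_index)]]
  ord <- stats::ave(seq_along(bout), bout, FUN = seq_along)
  summ <- do.call(rbind, lapply(split(sm$stride_time_s, ord), function(x) {
    data.frame(n = length(x), mean_s = mean(x),
               sd_s = if (length(x) > 1) stats::sd(x) else NA_real_)
  }))
  summ$order <- as.integer(rownames(summ))
  rownames(summ) <- NULL
  tab <- table(ord)
  test <- NULL
  usable <- names(tab)[tab >= 2]
  if (length(usable) >= 2L) {
    keep <- ord %in% as.integer(usable)
    test <- stats::kruskal.test(sm$stride_time_s[keep], factor(ord[keep]))
  }
  list(summary = summ[, c("order", "n", "mean_s", "sd_s")], test = test)
}
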