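test_that("footswitch events recover generator ground truth to one sample", {
  tr <- test_trial_kin()
  fs <- tr$kin$rate_Hz
  ev <- detect_events_fsr(tr$kin, fs)
  gt <- tr$ground_truth$events
  for (lab in c("LHS", "RTO", "RHS", "LTO")) {
    err <- event_errors(ev, gt, lab)
    expect_lte(max(err), 1 / fs + 1e-9)
  }
  expect_length(attr(ev, "quality"), 0)

  # flat heel channel -> quality flag, no heel events on that side
  flat <- tr$kin
  flat$fsr_heel_l <- rep(0, length(flat$fsr_heel_l))
  ev2 <- detect_events_fsr(flat, fs)
  expect_true("fsr_heel_l" %in% attr(ev2, "quality"))
  expect_equal(sum(ev2$label == "LHS"), 0)

  # noise-free square pulses: exactly one event per rising edge
  n <- 1000
  pulse <- rep(0, n)
  for (s in c(100, 400, 700)) pulse[s:(s + 150)] <- 1
  fake <- list(fsr_heel_l = pulse, fsr_met1_l = pulse, fsr_met5_l = pulse,
               fsr_toe_l = pulse, fsr_heel_r = pulse, fsr_met1_r = pulse,
               fsr_met5_r = pulse, fsr_toe_r = pulse)
  ev3 <- detect_events_fsr(fake, 100)
  expect_equal(sum(ev3$label == "LHS"), 3)
  expect_equal(sum(ev3$label == "LTO"), 3)
})

test_that("goniometer fallback detects events near truth and agrees with FSR", {
  tr <- test_trial_kin()
  fs <- tr$kin$rate_Hz
  gt <- tr$ground_truth$events
  evg <- detect_events_goniometer(tr$kin, fs)
  for (lab in c("LHS", "RTO", "RHS", "LTO")) {
    expect_lt(median(event_errors(evg, gt, lab)), 0.020)
  }

  # agreement with the footswitch detector on a clean trial
  evf <- detect_events_fsr(tr$kin, fs)
  d <- unlist(lapply(c("LHS", "LTO"), function(lab) {
    event_errors(evg, evf, lab)
  }))
  expect_lt(median(d), 0.020)

  # constant angle: no events, flagged
  const <- list(gonio_l = rep(5, 1000), gonio_r = rep(5, 1000))
  evc <- detect_events_goniometer(const, 100)
  expect_equal(nrow(evc), 0)
  expect_setequal(attr(evc, "quality"), c("gonio_l", "gonio_r"))
})

test_that("cycles are phase partitions and skip malformed event runs", {
  ev <- data.frame(
    time_s = c(0.00, 0.12, 0.62, 0.72, 1.10),
    label = c("LHS", "RTO", "RHS", "LTO", "LHS")
  )
  cyc <- build_cycles(ev)
  expect_equal(nrow(cyc), 1)
  expect_equal(cyc$lhs, 0)
  expect_equal(cyc$rto, 0.12)
  expect_equal(cyc$rhs, 0.62)
  expect_equal(cyc$lto, 0.72)
  expect_equal(cyc$lhs_next, 1.10)
  expect_equal(cyc$stride_time_s, 1.10)

  # partition: phase durations sum exactly to the stride time
  tr <- test_trial_kin()
  cyc2 <- build_cycles(tr$ground_truth$events)
  expect_equal((cyc2$rto - cyc2$lhs) + (cyc2$rhs - cyc2$rto) +
                 (cyc2$lto - cyc2$rhs) + (cyc2$lhs_next - cyc2$lto),
               cyc2$stride_time_s)

  # a missing RTO drops exactly that cycle
  ev3 <- data.frame(
    time_s = c(0.00, 0.12, 0.62, 0.72, 1.10, 1.70, 1.82, 2.20,
               2.32, 1.22, 2.72),
    label = c("LHS", "RTO", "RHS", "LTO", "LHS", "RHS", "LTO", "LHS",
              "RTO", "RTO", "RHS")
  )
  ev3 <- ev3[order(ev3$time_s), ]
  ev3 <- ev3[-which(ev3$label == "RTO" & ev3$time_s == 1.22), ]
  cyc3 <- build_cycles(ev3)
  expect_equal(cyc3$lhs, 0)
  expect_equal(nrow(cyc3), 1)
})

test_that("turn flagging matches ground truth and is a pure filter", {
  tr <- test_trial_kin()
  fs <- tr$kin$rate_Hz
  cyc <- build_cycles(tr$ground_truth$events)
  flagged <- exclude_turns(cyc, tr$kin$pelvis_heading, fs)
  expect_setequal(flagged$cycle_index[flagged$is_turn],
                  tr$ground_truth$turn_strides)
  # flagging does not alter timing columns of retained cycles
  keep <- flagged[!flagged$is_turn, c("lhs", "rto", "rhs", "lto",
                                      "lhs_next")]
  orig <- cyc[!flagged$is_turn, c("lhs", "rto", "rhs", "lto", "lhs_next")]
  expect_identical(keep, orig)

  # straight walking: nothing flagged
  sub <- test_subject()
  surf <- build_surface(sub, 1)
  tr2 <- simulate_trial(sub, surf, sub$clinical_setting, n_strides = 8,
                        seed = 4, turn_every = Inf, neural = FALSE)
  cyc2 <- exclude_turns(build_cycles(tr2$ground_truth$events),
                        tr2$kin$pelvis_heading, fs)
  expect_equal(sum(cyc2$is_turn), 0)

  expect_warning(exclude_turns(cyc, NULL, fs), "heading")
})

test_that("stride metrics follow their definitions", {
  # constant-velocity pelvis: 1.2 m over a 1.0 s stride
  cyc <- data.frame(lhs = 1, rto = 1.12, rhs = 1.5, lto = 1.62,
                    lhs_next = 2, stride_time_s = 1, cycle_index = 1L,
                    is_turn = FALSE)
  t <- seq(0, 3, by = 0.01)
  pelvis <- 1.2 * t
  wrist <- 0.2 * sin(2 * pi * t)
  sm <- compute_stride_metrics(cyc, pelvis, wrist, -wrist, 100)
  expect_equal(sm$stride_velocity, 1.2, tolerance = 0.02)
  expect_equal(sm$arm_swing_amplitude, 0.4, tolerance = 0.01)

  # stream gap inside the cycle drops the stride
  pelvis_na <- pelvis
  pelvis_na[150] <- NA
  sm2 <- compute_stride_metrics(cyc, pelvis_na, wrist, -wrist, 100)
  expect_equal(nrow(sm2), 0)
})

test_that("trial aggregation computes CVs by definition", {
  base <- data.frame(
    stride_index = 1:6, stride_time_s = 1, stride_length_m = 1.2,
    stride_velocity = 1.2, step_time_s = 0.5, step_length_m = 0.6,
    arm_swing_amplitude = 0.3, is_turn = FALSE
  )
  agg <- aggregate_trial_metrics(base)
  expect_equal(agg$step_time_cv, 0)
  expect_equal(agg$step_length_cv, 0)

  # hand-computed sample CV (ddof = 1): {0.5, 0.5, 0.6, 0.6}
  v <- base[1:4, ]
  v$step_time_s <- c(0.5, 0.5, 0.6, 0.6)
  agg2 <- aggregate_trial_metrics(v, min_strides = 4)
  expect_equal(agg2$step_time_cv, sd(c(0.5, 0.5, 0.6, 0.6)) / 0.55)

  # scale invariance of the CV
  v2 <- v
  v2$step_length_m <- v$step_length_m * 2
  expect_equal(aggregate_trial_metrics(v2, min_strides = 4)$step_length_cv,
               aggregate_trial_metrics(v, min_strides = 4)$step_length_cv)

  expect_false(aggregate_trial_metrics(base[1:3, ])$usable)
})

test_that("stride-order analysis is calibrated and powered", {
  make_strides <- function(n_bouts, per_bout, first_slow = 0) {
    idx <- 1L
    rows <- list()
    for (b in seq_len(n_bouts)) {
      for (k in seq_len(per_bout)) {
        st <- rnorm(1, 1.1, 0.05) * (1 + if (k == 1) first_slow else 0)
        rows[[length(rows) + 1L]] <- data.frame(
          stride_index = idx, stride_time_s = st, stride_length_m = 1,
          stride_velocity = 1, step_time_s = 0.55, step_length_m = 0.6,
          arm_swing_amplitude = 0.3, is_turn = FALSE
        )
        idx <- idx + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        stride_index = idx, stride_time_s = 1.2, stride_length_m = 1,
        stride_velocity = 1, step_time_s = 0.55, step_length_m = 0.6,
        arm_swing_amplitude = 0.3, is_turn = TRUE
      )
      idx <- idx + 1L
    }
    do.call(rbind, rows)
  }

  # type-I error control under no order effect
  set.seed(11)
  p_null <- replicate(100, {
    stride_order_consistency(make_strides(20, 5))$test$p.value
  })
  expect_gte(mean(p_null > 0.05), 0.90)

  # power against a 30% first-stride slowing
  set.seed(12)
  p_alt <- replicate(50, {
    stride_order_consistency(make_strides(20, 5, first_slow = 0.3))$test$p.value
  })
  expect_gte(mean(p_alt < 0.05), 0.90)

  # a single 3-stride bout gives three singleton orders and no test
  one <- make_strides(1, 3)
  one <- one[!one$is_turn, ]
  res <- stride_order_consistency(one)
  expect_null(res$test)
  expect_equal(nrow(res$summary), 3)
})
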