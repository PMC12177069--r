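test_that("surfaces are seeded, unimodal and correctly parameterized", {
  sub <- test_subject()
  s1 <- build_surface(sub, 42)
  s2 <- build_surface(sub, 42)
  expect_identical(s1, s2)

  # optimum evaluates to the peak
  expect_equal(true_wpi(s1, s1$optimum), s1$peak_wpi)
  expect_gt(s1$peak_wpi, s1$baseline_wpi)
  expect_true(all(s1$axis_widths > 0))

  # symmetry about the optimum along one axis
  o <- s1$optimum
  d <- 0.2
  up <- stim_setting(o$amplitude_mA + d, o$frequency_Hz, o$pulse_width_us)
  dn <- stim_setting(o$amplitude_mA - d, o$frequency_Hz, o$pulse_width_us)
  expect_equal(true_wpi(s1, up), true_wpi(s1, dn))

  # brute-force grid argmax lands within one grid cell of the optimum
  box <- sub$safe_range
  ax <- lapply(box, function(r) seq(r[1], r[2], length.out = 50))
  g <- expand.grid(a = ax[[1]], f = ax[[2]], p = ax[[3]])
  val <- s1$baseline_wpi + (s1$peak_wpi - s1$baseline_wpi) *
    exp(-0.5 * (((g$a - o$amplitude_mA) / s1$axis_widths[1])^2 +
                  ((g$f - o$frequency_Hz) / s1$axis_widths[2])^2 +
                  ((g$p - o$pulse_width_us) / s1$axis_widths[3])^2))
  i <- which.max(val)
  steps <- vapply(ax, function(a) diff(a[1:2]), numeric(1))
  expect_lte(abs(g$a[i] - o$amplitude_mA), steps[1])
  expect_lte(abs(g$f[i] - o$frequency_Hz), steps[2])
  expect_lte(abs(g$p[i] - o$pulse_width_us), steps[3])

  # corner value matches direct closed-form evaluation
  corner <- stim_setting(box$amplitude_mA[1], box$frequency_Hz[1],
                         box$pulse_width_us[1])
  cv3 <- c(box$amplitude_mA[1], box$frequency_Hz[1], box$pulse_width_us[1])
  r2 <- sum((cv3 - c(o$amplitude_mA, o$frequency_Hz, o$pulse_width_us))^2 /
              s1$axis_widths^2)
  expect_equal(true_wpi(s1, corner),
               s1$baseline_wpi +
                 (s1$peak_wpi - s1$baseline_wpi) * exp(-0.5 * r2))

  # out-of-box settings are rejected
  expect_error(true_wpi(s1, stim_setting(99, 130, 80)), "outside")
  bad <- sub
  bad$safe_range$amplitude_mA <- c(5, 5)
  expect_error(build_surface(bad, 1), "degenerate")
})

test_that("simulated trials honour the stride-count and event contracts", {
  expect_error(simulate_trial(test_subject(), build_surface(test_subject(), 1),
                              test_subject()$clinical_setting,
                              n_strides = 3, neural = FALSE),
               "n_strides")

  tr <- test_trial_kin()
  ev <- tr$ground_truth$events
  expect_true(all(diff(ev$time_s) > 0))
  cyc_l <- build_cycles(ev, "left")
  cyc_r <- build_cycles(ev, "right")
  expect_equal(nrow(cyc_l), 20)
  # 200-step configuration: both reference sides yield n_strides cycles
  sub <- test_subject()
  surf <- build_surface(sub, 1)
  tr200 <- simulate_trial(sub, surf, sub$clinical_setting, n_strides = 100,
                          seed = 9, neural = FALSE)
  ev200 <- tr200$ground_truth$events
  expect_equal(nrow(build_cycles(ev200, "left")), 100)
  expect_equal(nrow(build_cycles(ev200, "right")), 100)

  # stream lengths consistent with rates and trial duration
  n_kin <- length(tr$kin$time_s)
  expect_equal(length(tr$kin$pelvis_pos), n_kin)
  expect_equal(length(tr$kin$fsr_heel_l), n_kin)
})

test_that("trial kinematics invert the index metrics (Monte-Carlo closure)", {
  sub <- test_subject()
  surf <- build_surface(sub, 4)
  setting <- sub$clinical_setting
  res <- lapply(1:50, function(s) {
    tr <- simulate_trial(sub, surf, setting, n_strides = 20, seed = s,
                         neural = FALSE)
    agg <- aggregate_trial_metrics(stimgait:::trial_stride_metrics(tr))
    tg <- tr$ground_truth$metric_targets
    c(sv = agg$stride_velocity - tg$stride_velocity,
      as = agg$arm_swing_amplitude - tg$arm_swing,
      vst = agg$step_time_cv - tg$step_time_cv,
      vsl = agg$step_length_cv - tg$step_length_cv)
  })
  err <- do.call(rbind, res)
  # mean recovery error within 3 SE of zero for every metric, allowing the
  # small-sample downward bias of the sample CV (~CV/(4 n) at n = 16)
  for (j in 1:4) {
    se <- sd(err[, j]) / sqrt(nrow(err))
    expect_lt(abs(mean(err[, j])), 3 * se + 5e-3)
  }
})

test_that("artifact injection is bookkept and spectrally correct", {
  tr <- test_trial_neural()
  expect_identical(inject_artifacts(tr, list()), tr)

  tr_g <- inject_artifacts(tr, list(gamma_burst = list(z = 12, n = 5)),
                           seed = 8)
  gt <- tr_g$ground_truth$artifacts
  expect_equal(sum(gt$kind == "gamma_burst"), 5)
  expect_true(all(gt$start >= 0 & gt$end <= length(tr$neural$left$GP) / 500))

  # stimulation tone: spectral peaks at the stim frequency and subharmonic
  tr_s <- inject_artifacts(tr, list(stim_tone = list(frequency_Hz = 130,
                                                     amplitude = 1)),
                           seed = 8)
  x <- tr_s$neural$left$GP
  n <- length(x)
  pw <- Mod(fft(x - mean(x)))^2
  fax <- (0:(n - 1)) / n * 500
  at <- function(f) max(pw[abs(fax - f) < 0.5])
  bg <- median(pw[fax > 100 & fax < 125])
  expect_gt(at(130) / bg, 100)
  expect_gt(at(65) / bg, 25)

  expect_error(inject_artifacts(tr, list(bogus = list())), "unknown")
})

test_that("cohorts have the declared shape, implant pattern and determinism", {
  coh <- test_cohort_kin()
  man <- coh$manifest
  expect_equal(nrow(man), 3 * 2 * 4)
  expect_equal(sum(man$clinical), 3 * 2)
  expect_true(all(tapply(man$clinical, man$visit_id, sum) == 1))

  coh2 <- simulate_cohort(cohort_config(n_visits = 2, n_settings = 4,
                                        n_strides = 12, neural = FALSE),
                          seed = 5)
  expect_identical(coh$manifest, coh2$manifest)

  # implant pattern: bilateral, bilateral, unilateral
  cc <- cohort_config(n_visits = 1, n_settings = 2, n_strides = 4,
                      neural = TRUE)
  cohn <- simulate_cohort(cc, seed = 2)
  hemis <- vapply(cohn$subjects, function(s) s$hemispheres, integer(1))
  expect_equal(hemis, c(2L, 2L, 1L))
  for (tid in cohn$manifest$trial_id) {
    tr <- cohn$trials[[tid]]
    expect_equal(length(tr$neural),
                 hemis[match(tr$subject_id, vapply(cohn$subjects,
                                                   `[[`, "", "subject_id"))])
  }
})

test_that("feedback rankings span perfect concordance to pure noise", {
  coh <- test_cohort_kin()
  fb1 <- simulate_feedback(coh, concordance = 1, seed = 3,
                           raters = "patient")
  expect_equal(fb1$feedback_rank, fb1$true_wpi_rank)
  expect_true(all(vapply(split(fb1$feedback_rank, fb1$visit_id),
                         function(r) setequal(r, seq_along(r)),
                         logical(1))))

  # concordance 0: rank of a fixed trial uniform across seeds
  vid <- coh$manifest$visit_id[1]
  n_tr <- sum(coh$manifest$visit_id == vid)
  first <- vapply(1:500, function(s) {
    fb <- simulate_feedback(coh, concordance = 0, seed = s,
                            raters = "patient")
    fb$feedback_rank[fb$visit_id == vid][1]
  }, integer(1))
  tab <- tabulate(first, n_tr)
  p <- chisq.test(tab)$p.value
  expect_gt(p, 0.01)

  expect_error(simulate_feedback(coh, concordance = 2), "concordance")
})
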