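test_that("clock synchronization recovers injected offsets", {
  tr <- test_trial_neural() # offset 3.2 s
  sy <- estimate_sync(tr$device_accel,
                      list(time_s = tr$kin$time_s,
                           value = tr$kin$chest_accel))
  expect_lt(abs(sy$offset_s - 3.2), 1 / 64)
  expect_gte(sy$n_anchors, 1)

  # identical streams: zero offset
  w <- list(time_s = tr$kin$time_s, value = tr$kin$chest_accel)
  sy0 <- estimate_sync(w, w)
  expect_equal(sy0$offset_s, 0)

  # disjoint content fails
  set.seed(1)
  flat <- list(time_s = seq(0, 10, by = 1 / 64),
               value = rnorm(641, 0, 1e-4))
  expect_error(estimate_sync(flat, w), "synchron|peak")

  # property: offsets U(-5, 5) recovered within 2 device samples
  errs <- vapply(1:40, function(s) {
    set.seed(s)
    off <- runif(1, -5, 5)
    pk <- cumsum(runif(12, 0.9, 1.3)) + 6
    tw <- seq(0, 25, by = 0.01)
    td <- seq(0, 25, by = 1 / 64)
    bump <- function(t, centers) {
      rowSums(vapply(centers, function(c0) {
        1.5 * exp(-0.5 * ((t - c0) / 0.05)^2)
      }, numeric(length(t))))
    }
    wv <- list(time_s = tw, value = bump(tw, pk) + rnorm(length(tw), 0, 0.02))
    dv <- list(time_s = td, value = bump(td, pk + off) +
                 rnorm(length(td), 0, 0.02))
    abs(estimate_sync(dv, wv)$offset_s - off)
  }, numeric(1))
  expect_lte(max(errs), 2 / 64)
})

test_that("anchor statistics summarize amplitudes and inter-arrival times", {
  ev <- data.frame(time_s = seq(0, 11, by = 1.1), amplitude = 1.5)
  st <- anchor_stats(ev)
  expect_equal(st$pooled$iat_sd, 0)
  expect_equal(st$pooled$iat_mean, 1.1)

  one <- data.frame(time_s = 1, amplitude = 2)
  st1 <- anchor_stats(one)
  expect_equal(st1$pooled$amp_mean, 2)
  expect_true(is.na(st1$pooled$iat_mean))

  # generator cohort: inter-arrival mean tracks the stride period
  tr <- test_trial_neural()
  pk_t <- stimgait:::accel_peaks(tr$kin$chest_accel, 100)
  st2 <- anchor_stats(data.frame(time_s = pk_t, amplitude = 1))
  sub <- test_subject()
  expect_lt(abs(st2$pooled$iat_mean - sub$stride_period_s) /
              sub$stride_period_s, 0.05)
})

test_that("the high-pass filter removes drift and preserves passband", {
  fs <- 500
  t <- (0:(10 * fs - 1)) / fs
  x <- 2 + sin(2 * pi * 20 * t)
  y <- highpass(x, fs, 1)
  # DC (offset 2) removed to below 1% of the offset
  expect_lt(abs(mean(y)), 0.02)
  # 20 Hz amplitude preserved within 1% (FFT amplitude oracle)
  amp_at <- function(sig, f) {
    n <- length(sig)
    2 * Mod(fft(sig))[round(f * n / fs) + 1] / n
  }
  expect_equal(amp_at(y, 20), 1, tolerance = 0.01)

  # 0.2 Hz drift attenuated by >= 20 dB
  d <- sin(2 * pi * 0.2 * t)
  expect_lt(amp_at(highpass(d, fs, 1), 0.2), 10^(-20 / 20))

  expect_equal(highpass(rep(0, fs * 2), fs, 1), rep(0, fs * 2))
  expect_error(highpass(x, fs, 300), "Nyquist")
})

test_that("gamma outlier masking hits bursts, spares clean data, is strict", {
  tr <- test_trial_neural()
  tr_b <- inject_artifacts(tr, list(gamma_burst = list(z = 12, n = 5)),
                           seed = 6)
  x <- tr_b$neural$left$GP
  gm <- gamma_outlier_mask(x, 500)
  gt <- tr_b$ground_truth$artifacts
  # every injected burst is flagged, every above-threshold sample is
  # masked, and each sits at least the 200 ms buffer away from its
  # interval's edges
  for (i in seq_len(nrow(gt))) {
    hit <- gm$intervals$start_s <= gt$start[i] &
      gm$intervals$end_s >= gt$end[i]
    expect_true(any(hit))
  }
  flagged_t <- (which(abs(gm$z) > 8) - 1) / 500
  expect_gt(length(flagged_t), 0)
  for (t0 in flagged_t) {
    j <- which(gm$intervals$start_s <= t0 & gm$intervals$end_s > t0)
    expect_length(j, 1)
    expect_gte(t0 - gm$intervals$start_s[j], 0.2 - 2 / 500)
    expect_gte(gm$intervals$end_s[j] - t0, 0.2 - 2 / 500)
  }

  # clean signal: empty mask
  gm0 <- gamma_outlier_mask(tr$neural$left$GP, 500)
  expect_equal(sum(gm0$mask), 0)

  # strict inequality at the threshold: a run whose max |z| equals the
  # threshold is not flagged; just below the max it is
  zmax <- max(abs(gm$z), na.rm = TRUE)
  at_thr <- gamma_outlier_mask(x, 500, z_threshold = zmax)
  expect_equal(nrow(at_thr$intervals), 0)
  below <- gamma_outlier_mask(x, 500, z_threshold = zmax - 1e-6)
  expect_gt(nrow(below$intervals), 0)

  short <- rnorm(100)
  expect_warning(m <- gamma_outlier_mask(short, 500), "shorter")
  expect_equal(sum(m$mask), 0)
})

test_that("blanking is exact, idempotent and length-checked", {
  x <- rnorm(1000)
  m <- stimgait:::empty_mask(1000, 500)
  expect_identical(apply_blanking(x, m), x)
  m$mask[101:200] <- TRUE
  y <- apply_blanking(x, m)
  expect_true(all(is.na(y[101:200])))
  expect_identical(y[-(101:200)], x[-(101:200)])
  expect_identical(apply_blanking(y, m), y)
  full <- rep(TRUE, 1000)
  expect_true(all(is.na(apply_blanking(x, full))))
  expect_error(apply_blanking(x, full[1:10]), "length")
})

test_that("packet loss is detected as frozen runs with the merge rule", {
  set.seed(7)
  x <- rnorm(5000)
  x[1001:1060] <- x[1000] # 120 ms frozen at 500 Hz
  ints <- detect_packet_loss(x, 500)
  expect_equal(nrow(ints), 1)
  expect_lte(ints$start_s, 2.0)
  expect_gte(ints$end_s, 2.12 - 0.01)

  expect_equal(nrow(detect_packet_loss(rnorm(5000), 500)), 0)

  # two gaps 30 ms apart merge (< 50 ms merge rule)
  y <- rnorm(5000)
  y[2001:2030] <- y[2000]
  y[2046:2075] <- y[2045]
  m2 <- detect_packet_loss(y, 500, min_run_s = 0.05)
  expect_equal(nrow(m2), 1)
})

test_that("contaminated cycles are excluded by the phase rules", {
  cyc <- build_cycles(data.frame(
    time_s = c(0, 0.12, 0.62, 0.72, 1.1, 1.22, 1.72, 1.82, 2.2),
    label = c("LHS", "RTO", "RHS", "LTO", "LHS", "RTO", "RHS", "LTO", "LHS")
  ))
  expect_equal(nrow(cyc), 2)

  none <- exclude_contaminated_cycles(cyc, NULL, NULL)
  expect_equal(nrow(none), 2)

  # packet loss inside cycle 1 only
  pl <- data.frame(start_s = 0.5, end_s = 0.55, provenance = "packet_loss")
  kept <- exclude_contaminated_cycles(cyc, NULL, pl)
  expect_equal(kept$cycle_index, 2L)
  expect_equal(attr(kept, "dropped")$reason, "packet_loss")

  # gamma blanking covering 60% of DS2 drops the cycle; 40% keeps it
  ds2 <- c(cyc$rhs[1], cyc$lto[1])
  g60 <- data.frame(start_s = ds2[1], end_s = ds2[1] + 0.6 * diff(ds2),
                    provenance = "gamma_outlier")
  g40 <- data.frame(start_s = ds2[1], end_s = ds2[1] + 0.4 * diff(ds2),
                    provenance = "gamma_outlier")
  expect_equal(exclude_contaminated_cycles(cyc, g60, NULL)$cycle_index, 2L)
  expect_equal(nrow(exclude_contaminated_cycles(cyc, g40, NULL)), 2)
})
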