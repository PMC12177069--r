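test_that("the scalogram localizes frequency and scales quadratically", {
  fs <- 500
  t <- (0:(8 * fs - 1)) / fs
  x <- sin(2 * pi * 20 * t)
  m <- cwt_power(x, fs, 4, 30)
  ridge <- m$freq_Hz[which.max(rowMeans(m$values, na.rm = TRUE))]
  # within half a voice (10 voices/octave) of 20 Hz
  expect_lt(abs(log2(ridge / 20)), 0.5 / 10)

  m2 <- cwt_power(2 * x, fs, 4, 30)
  expect_equal(max(rowMeans(m2$values, na.rm = TRUE)),
               4 * max(rowMeans(m$values, na.rm = TRUE)), tolerance = 1e-6)

  z <- cwt_power(rep(0, 4 * fs), fs, 4, 30)
  expect_true(all(z$values[!is.na(z$values)] == 0))

  # all-missing signal gives an empty map
  e <- cwt_power(rep(NA_real_, fs), fs, 4, 30)
  expect_equal(ncol(e$values), 0)
})

test_that("wavelet coherence separates coupled from independent signals", {
  fs <- 250
  t <- (0:(8 * fs - 1)) / fs
  set.seed(5)
  s <- sin(2 * pi * 10 * t)
  x <- s + rnorm(length(t), 0, 0.2)
  co_self <- wavelet_coherence(x, x, fs, 4, 30)
  expect_gt(median(co_self$values, na.rm = TRUE), 0.99)

  co_null <- wavelet_coherence(rnorm(length(t)), rnorm(length(t)), fs, 4, 30)
  expect_lt(median(co_null$values, na.rm = TRUE), 0.5)

  # constant-lag copy stays coherent at the signal band
  y <- c(rep(0, 25), head(x, -25)) + rnorm(length(t), 0, 0.2)
  co_lag <- wavelet_coherence(x, y, fs, 4, 30)
  row10 <- which.min(abs(co_lag$freq_Hz - 10))
  expect_gt(median(co_lag$values[row10, ], na.rm = TRUE), 0.9)

  expect_true(all(co_null$values[!is.na(co_null$values)] >= 0 &
                    co_null$values[!is.na(co_null$values)] <= 1))
})

test_that("per-frequency z-scoring pools a visit and handles degeneracy", {
  fs <- 100
  mk <- function(seed) {
    set.seed(seed)
    cwt_power(rnorm(4 * fs), fs, 4, 30)
  }
  maps <- list(mk(1), mk(2))
  zm <- zscore_per_frequency(maps)
  for (i in seq_along(zm[[1]]$freq_Hz)) {
    vals <- c(zm[[1]]$values[i, ], zm[[2]]$values[i, ])
    vals <- vals[is.finite(vals)]
    expect_lt(abs(mean(vals)), 1e-8)
    expect_equal(sd(vals), 1, tolerance = 1e-6)
  }

  # affine transform of a row yields identical z rows
  m3 <- maps
  m3[[1]]$values[3, ] <- 2 * maps[[1]]$values[3, ] + 5
  m3[[2]]$values[3, ] <- 2 * maps[[2]]$values[3, ] + 5
  z3 <- zscore_per_frequency(m3)
  expect_equal(z3[[1]]$values[3, ], zm[[1]]$values[3, ], tolerance = 1e-9)

  # constant row flagged and zeroed
  m4 <- maps
  m4[[1]]$values[2, ] <- 1
  m4[[2]]$values[2, ] <- 1
  z4 <- zscore_per_frequency(m4)
  expect_true(all(z4[[1]]$values[2, ] == 0, na.rm = TRUE))
  expect_equal(attr(z4, "constant_rows"), m4[[1]]$freq_Hz[2])

  # z-normalization preserves within-row ordering
  ord_raw <- order(maps[[1]]$values[5, ])
  ord_z <- order(zm[[1]]$values[5, ])
  expect_equal(ord_raw, ord_z)
})

test_that("band definitions tile [2,30) with inclusive lower bounds", {
  b <- canonical_bands()
  edges <- sort(unique(unlist(b)))
  expect_equal(edges, c(2, 4, 8, 12, 30))
  # every frequency in [2, 30) belongs to exactly one band
  f_test <- c(2, 3.99, 4, 7.5, 8, 11.99, 12, 29.99)
  counts <- vapply(f_test, function(f) {
    sum(vapply(b, function(r) f >= r[1] && f < r[2], logical(1)))
  }, numeric(1))
  expect_true(all(counts == 1))

  # a grid row at exactly 12 Hz contributes to beta, not alpha
  map <- structure(
    list(kind = "power",
         values = matrix(c(1, 2, 3), nrow = 3, ncol = 4),
         freq_Hz = c(10, 12, 20), time_s = (0:3) / 10, rate_Hz = 10,
         normalization = "raw"),
    class = "tf_map"
  )
  expect_equal(band_average(map, "beta"), rep(mean(c(2, 3)), 4))
  expect_equal(band_average(map, "alpha"), rep(1, 4))
  expect_error(band_average(map, "delta"), "delta")
  expect_error(band_average(map, "gamma_low"), "unknown band")
})

test_that("phase averages are exact on step constructions", {
  cyc <- build_cycles(data.frame(
    time_s = c(1.0, 1.12, 1.5, 1.62, 2.0),
    label = c("LHS", "RTO", "RHS", "LTO", "LHS")
  ))
  rate <- 100
  series <- rep(0, 300)
  tt <- (0:299) / rate
  series[tt >= 1.0 & tt < 1.5] <- 1
  series[tt >= 1.5 & tt < 2.0] <- 3
  pa <- phase_average(series, rate, cyc)
  expect_equal(unname(pa$per_trial["DS1"]), 1)
  expect_equal(unname(pa$per_trial["CLS"]), 1)
  expect_equal(unname(pa$per_trial["DS2"]), 3)
  expect_equal(unname(pa$per_trial["ILS"]), 3)

  # constant series: every phase equals the constant
  pc <- phase_average(rep(7, 300), rate, cyc)
  expect_true(all(pc$per_trial == 7))

  # a phase with > 50% missing becomes missing
  s2 <- series
  s2[tt >= 1.5 & tt < 1.58] <- NA # 8 of 12 DS2 samples
  pm <- phase_average(s2, rate, cyc)
  expect_true(is.na(pm$per_cycle$value[pm$per_cycle$phase == "DS2"]))
})

test_that("phase-gated beta envelopes produce the configured DS2/CLS contrast", {
  # planned phase constants put CLS above DS2; check the realized features
  ok <- vapply(1:5, function(s) {
    sub <- test_subject()
    surf <- build_surface(sub, s)
    tr <- simulate_trial(sub, surf, sub$clinical_setting, n_strides = 10,
                         seed = s, neural = TRUE)
    x <- highpass(tr$neural$left$GP, 500, 1)
    m <- cwt_power(x, 500, 12, 30)
    zm <- zscore_per_frequency(list(m))[[1]]
    cyc <- build_cycles(tr$ground_truth$events)
    cyc <- cyc[!cyc$cycle_index %in% tr$ground_truth$turn_strides, ]
    pa <- phase_average(band_average(zm, "beta"), 500, cyc)
    pa$per_trial["DS2"] < pa$per_trial["CLS"]
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})

test_that("stride-time sorting is ascending and stable", {
  expect_equal(sort_by_stride_time(c(1.2, 1.0, 1.1)), c(2, 3, 1))
  expect_equal(sort_by_stride_time(c(1, 2, 3)), 1:3)
  expect_equal(sort_by_stride_time(c(1, 1, 1)), 1:3)
})

test_that("the feature table joins manifest and round-trips losslessly", {
  fe <- data.frame(
    subject_id = "S1", hemisphere = "left", site_or_pair = "GP",
    kind = "power", band = "beta", phase = rep(c("DS1", "CLS", "DS2",
                                                 "ILS"), 2),
    trial_id = rep(c("t1", "t2"), each = 4), visit_id = "v1",
    value = rnorm(8)
  )
  wpi <- data.frame(trial_id = c("t1", "t2"), baseline_normalized = c(1, 1.2))
  man <- data.frame(trial_id = c("t1", "t2"), amplitude_mA = 5,
                    frequency_Hz = 130, pulse_width_us = 60,
                    clinical = c(TRUE, FALSE))
  ft <- build_feature_table(fe, wpi, man)
  expect_equal(nrow(ft), 8)
  expect_equal(ft$wpi[1:4], rep(1, 4))

  man_bad <- man[1, ]
  expect_error(build_feature_table(fe, wpi, man_bad), "t2")

  path <- tempfile(fileext = ".csv")
  write_table(ft, path)
  back <- read_table(path)
  expect_equal(back$value, ft$value, tolerance = 1e-12)

  # row-count bound: sites+pairs x bands x phases x trials
  expect_lte(nrow(ft), 1 * 1 * 4 * 2)
})
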