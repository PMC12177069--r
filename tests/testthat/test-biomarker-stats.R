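test_that("BH adjustment matches the brute-force step-up definition", {
  bh_brute <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(m)
    out[o] <- pmin(adj, 1)
    out
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.005, 0.1)), c(0.01, 0.1))
  set.seed(41)
  for (i in 1:1000) {
    p <- runif(sample(1:30, 1))
    expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

make_phase_features <- function(n, beta = c(0, 0, 0, 0), noise = 1,
                                seed = 1, subject = "S1") {
  set.seed(seed)
  ph <- matrix(rnorm(4 * n), ncol = 4,
               dimnames = list(NULL, c("DS1", "CLS", "DS2", "ILS")))
  wpi <- 1 + drop(ph %*% beta) + rnorm(n, 0, noise)
  long <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(subject_id = subject, hemisphere = "left",
               site_or_pair = "GP", band = "beta",
               phase = colnames(ph), trial_id = paste0("t", i),
               value = ph[i, ], wpi = wpi[i])
  }))
  rownames(long) <- NULL
  long
}

test_that("per-subject phase models recover a planted phase effect", {
  hit <- vapply(1:100, function(s) {
    ft <- make_phase_features(14, beta = c(0, 0, 0, 1.4), noise = 0.5,
                              seed = s)
    res <- fit_subject_phase_models(ft, min_trials = 8)
    ils <- res[res$phase == "ILS", ]
    ci <- c(ils$estimate - 2.26 * ils$se, ils$estimate + 2.26 * ils$se)
    ci[1] <= 1.4 && ci[2] >= 1.4
  }, logical(1))
  expect_gte(mean(hit), 0.90)

  # duplicated phase column is flagged
  ft <- make_phase_features(12, seed = 5)
  ft$value[ft$phase == "CLS"] <- ft$value[ft$phase == "DS1"]
  res <- fit_subject_phase_models(ft, min_trials = 8)
  expect_true(all(res$flagged))
})

test_that("per-subject model families control the false discovery rate", {
  disc <- unlist(lapply(1:500, function(s) {
    ft <- make_phase_features(12, seed = s + 1000)
    res <- fit_subject_phase_models(ft, min_trials = 8)
    res$p_adjusted < 0.05
  }))
  expect_lte(mean(disc), 0.05)
})

test_that("group mixed models recover slopes and control type-I error", {
  # recovery at the reported effect scale: n ~ 72, slope -0.22
  est <- vapply(1:100, function(s) {
    d <- simulate_phase_features(n_subjects = 3, n_visits = 4,
                                 n_trials = 3, slope = -0.22, seed = s)
    fit_group_feature_model(d$feature, d$wpi, d$subject_id,
                            d$hemisphere)$estimate
  }, numeric(1))
  expect_gte(mean(abs(est + 0.22) <= 0.1), 0.80)
  expect_lt(mean(est), 0)

  # type-I error of the LRT under a zero-slope feature, in the regime
  # where the chi-square reference applies (the few-cluster study scale
  # runs slightly anti-conservative and is exercised in the end-to-end
  # validation)
  rej <- vapply(1:500, function(s) {
    set.seed(s)
    n_sub <- 12
    n_per <- 20
    sub <- rep(paste0("S", 1:n_sub), each = n_per)
    wpi <- rep(rnorm(n_sub, 1, 0.1), each = n_per) +
      rnorm(n_sub * n_per, 0, 0.2)
    hemi <- rep(c("left", "right"), n_sub * n_per / 2)
    fit_group_feature_model(rnorm(n_sub * n_per), wpi, sub,
                            hemi)$p_lrt < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.06)

  expect_error(fit_group_feature_model(rnorm(30), rnorm(30),
                                       rep(c("a", "b"), 15)),
               ">= 3 subjects")
})

test_that("mixed estimates reduce to OLS when clustering vanishes", {
  d <- simulate_phase_features(n_subjects = 4, n_visits = 3, n_trials = 3,
                               slope = -0.22, subject_sd = 0, seed = 9)
  gm <- fit_group_feature_model(d$feature, d$wpi, d$subject_id,
                                d$hemisphere)
  ols <- lm(wpi ~ feature + hemisphere, data = d)
  # with no subject-level variance the fixed effect matches OLS closely
  expect_equal(gm$estimate, unname(coef(ols)["feature"]), tolerance = 0.02)
})

test_that("hemisphere interaction checks behave under both regimes", {
  mk <- function(seed, flip) {
    set.seed(seed)
    n <- 40
    sub <- rep(paste0("S", 1:4), each = n / 4)
    hemi <- rep(c("left", "right"), n / 2)
    f <- rnorm(n)
    slope <- ifelse(hemi == "left", -0.5, ifelse(flip, 0.5, -0.5))
    wpi <- 1 + slope * f + rnorm(n, 0, 0.3)
    list(f = f, wpi = wpi, sub = sub, hemi = hemi)
  }
  # same slope in both hemispheres: interaction does not improve fit
  delta <- vapply(1:60, function(s) {
    d <- mk(s, flip = FALSE)
    hemisphere_interaction_check(d$f, d$wpi, d$sub, d$hemi)$delta_aic
  }, numeric(1))
  expect_gt(mean(delta > 0), 0.5)

  # opposite slopes: interaction detected
  pows <- vapply(1:60, function(s) {
    d <- mk(s, flip = TRUE)
    hemisphere_interaction_check(d$f, d$wpi, d$sub, d$hemi)$interaction_p
  }, numeric(1))
  expect_gte(mean(pows < 0.05), 0.90)

  # order invariance of delta AIC
  d <- mk(3, flip = FALSE)
  a <- hemisphere_interaction_check(d$f, d$wpi, d$sub, d$hemi)$delta_aic
  o <- sample(length(d$f))
  b <- hemisphere_interaction_check(d$f[o], d$wpi[o], d$sub[o],
                                    d$hemi[o])$delta_aic
  expect_equal(a, b, tolerance = 1e-8)

  uni <- hemisphere_interaction_check(d$f, d$wpi, d$sub,
                                      rep("left", length(d$f)))
  expect_true(uni$skipped)
})

test_that("backward elimination keeps true features and drops nulls", {
  mk <- function(seed, true_beta) {
    set.seed(seed)
    n <- 60
    sub <- rep(paste0("S", 1:3), each = n / 3)
    F <- matrix(rnorm(n * 5), ncol = 5,
                dimnames = list(NULL, paste0("f", 1:5)))
    wpi <- 1 + true_beta * F[, 1] + rnorm(n, 0, 0.4)
    list(F = as.data.frame(F), wpi = wpi, sub = sub)
  }
  kept_true <- vapply(1:40, function(s) {
    d <- mk(s, 0.6)
    "f1" %in% backward_select(d$F, d$wpi, d$sub)
  }, logical(1))
  expect_gte(mean(kept_true), 0.85)

  empty <- vapply(1:40, function(s) {
    d <- mk(s + 500, 0)
    length(backward_select(d$F, d$wpi, d$sub)) == 0
  }, logical(1))
  expect_gte(mean(empty), 0.70)

  # single feature reduces to the LRT decision
  d <- mk(1, 0.6)
  one <- backward_select(d$F[, 1, drop = FALSE], d$wpi, d$sub)
  expect_equal(as.character(one), "f1")
})

test_that("residual diagnostics are calibrated and powered", {
  p_null <- vapply(1:500, function(s) {
    set.seed(s)
    residual_diagnostics(rnorm(70))$shapiro_p
  }, numeric(1))
  ks <- ks.test(p_null, "punif")
  expect_gt(ks$p.value, 0.01)

  p_exp <- vapply(1:100, function(s) {
    set.seed(s)
    residual_diagnostics(rexp(70) - 1)$shapiro_p
  }, numeric(1))
  expect_gte(mean(p_exp < 0.05), 0.95)

  sk <- vapply(1:100, function(s) {
    set.seed(s)
    residual_diagnostics(rnorm(500))$skewness
  }, numeric(1))
  expect_lt(mean(abs(sk)), 0.2)

  short <- residual_diagnostics(rnorm(5))
  expect_true(short$descriptive_only)
})

test_that("the feedback-rank model tracks concordance", {
  # perfectly concordant ranks give slope 1 and a tiny p
  wr <- rep(1:4, 6)
  sub <- rep(c("S1", "S2", "S3"), each = 8)
  fm <- feedback_rank_model(wr, wr, sub)
  expect_equal(fm$slope, 1, tolerance = 1e-8)
  expect_lt(fm$p, 1e-6)

  # noisy concordance keeps a positive slope in most seeds
  coh <- test_cohort_kin()
  pos <- vapply(1:50, function(s) {
    fb <- simulate_feedback(coh, concordance = 0.8, seed = s,
                            raters = "patient")
    feedback_rank_model(fb$true_wpi_rank, fb$feedback_rank,
                        fb$subject_id)$slope > 0
  }, logical(1))
  expect_gte(mean(pos), 0.95)

  # independent ranks: CI covers zero most of the time
  cover <- vapply(1:50, function(s) {
    fb <- simulate_feedback(coh, concordance = 0, seed = s,
                            raters = "patient")
    m <- feedback_rank_model(fb$true_wpi_rank, fb$feedback_rank,
                             fb$subject_id)
    abs(m$slope) <= 2 * m$se
  }, logical(1))
  expect_gte(mean(cover), 0.85)

  expect_error(feedback_rank_model(rep(1, 10), rep(1:2, 5),
                                   rep("S1", 10)), "constant")
})
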