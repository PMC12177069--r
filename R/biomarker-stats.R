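#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: adjusted p-values are
#' monotone in rank order and capped at 1. Input p-values must lie in
#' [0, 1].
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Per-subject phase-predictor regressions
#'
#' For each (subject, recording site or coherence pair, band) cell, fits
#' an ordinary least-squares model of WPI on the four gait-phase features
#' simultaneously (plus a hemisphere indicator for bilateral subjects),
#' identifying the phase most strongly associated with walking
#' performance. The BH family is the four phase p-values within each
#' model. Rank-deficient models (collinear phases) are flagged and
#' excluded from the family.
#'
#' @param features Long feature table with columns `subject_id`,
#'   `hemisphere`, `site_or_pair`, `band`, `phase`, `trial_id`, `value`,
#'   `wpi`.
#' @param min_trials Minimum complete-case trials per model (default 8).
#' @return Data frame, one row per (subject, site_or_pair, band, phase):
#'   estimate, SE, model R^2, raw and BH-adjusted p, plus a `flagged`
#'   column for rank-deficient models.
#' @export
fit_subject_phase_models <- function(features, min_trials = 8) {
  rows <- list()
  cells <- unique(features[, c("subject_id", "site_or_pair", "band")])
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    sub <- features[features$subject_id == cell$subject_id &
                      features$site_or_pair == cell$site_or_pair &
                      features$band == cell$band, , drop = FALSE]
    wide <- stats::reshape(
      sub[, c("trial_id", "hemisphere", "phase", "value", "wpi")],
      idvar = c("trial_id", "hemisphere", "wpi"),
      timevar = "phase", direction = "wide"
    )
    names(wide) <- sub("^value\\.", "", names(wide))
    wide <- wide[stats::complete.cases(wide[, GAIT_PHASES]), , drop = FALSE]
    if (nrow(wide) < min_trials) next
    bilateral <- length(unique(wide$hemisphere)) > 1L
    form <- if (bilateral) {
      wpi ~ DS1 + CLS + DS2 + ILS + hemisphere
    } else {
      wpi ~ DS1 + CLS + DS2 + ILS
    }
    fit <- stats::lm(form, data = wide)
    sm <- summary(fit)
    co <- sm$coefficients
    flagged <- anyNA(coef(fit)) || !all(GAIT_PHASES %in% rownames(co))
    if (flagged) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = cell$subject_id, site_or_pair = cell$site_or_pair,
        band = cell$band, phase = GAIT_PHASES, estimate = NA_real_,
        se = NA_real_, r_squared = sm$r.squared, p_value = NA_real_,
        p_adjusted = NA_real_, n = nrow(wide), flagged = TRUE
      )
      next
    }
    pvals <- co[GAIT_PHASES, "Pr(>|t|)"]
    padj <- bh_adjust(pvals)
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = cell$subject_id, site_or_pair = cell$site_or_pair,
      band = cell$band, phase = GAIT_PHASES,
      estimate = co[GAIT_PHASES, "Estimate"],
      se = co[GAIT_PHASES, "Std. Error"],
      r_squared = sm$r.squared, p_value = pvals, p_adjusted = padj,
      n = nrow(wide), flagged = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(subject_id = character(0), site_or_pair = character(0),
               band = character(0), phase = character(0),
               estimate = numeric(0), se = numeric(0),
               r_squared = numeric(0), p_value = numeric(0),
               p_adjusted = numeric(0), n = integer(0), flagged = logical(0))
  }
  rownames(out) <- NULL
  out
}

#' Group-level mixed-effects model for one neural feature
#'
#' Linear mixed model `wpi ~ feature + hemisphere + (1 | subject)`:
#' a fixed effect for the feature and for hemisphere with a random
#' intercept per subject. The Wald t statistic uses residual degrees of
#' freedom (n - number of fixed effects), and the feature's contribution
#' is additionally tested by a likelihood-ratio test against the null
#' model without the feature (both refitted by maximum likelihood).
#' Singular random-effect fits fall back to OLS with a flag.
#'
#' @param feature Numeric feature values (z units), one per observation.
#' @param wpi Baseline-normalized WPI per observation.
#' @param subject Subject id per observation (>= 3 subjects).
#' @param hemisphere Hemisphere label per observation (optional; omitted
#'   from the model when constant).
#' @return A `group_model_result` list: `estimate`, `se`, `t`, `df`,
#'   `p_wald`, `lrt_chisq`, `lrt_df`, `p_lrt`, `aic`, `n`, `singular`,
#'   `model`.
#' @export
fit_group_feature_model <- function(feature, wpi, subject,
                                    hemisphere = NULL) {
  dat <- data.frame(wpi = wpi, feature = feature,
                    subject = factor(subject))
  if (!is.null(hemisphere)) dat$hemisphere <- factor(hemisphere)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (nlevels(droplevels(dat$subject)) < 3L) {
    stop("group model needs >= 3 subjects")
  }
  if (n < 20L) stop("group model needs >= 20 observations")
  use_hemi <- !is.null(dat$hemisphere) &&
    nlevels(droplevels(dat$hemisphere)) > 1L
  fixed <- if (use_hemi) "feature + hemisphere" else "feature"
  f_full <- stats::as.formula(paste("wpi ~", fixed, "+ (1 | subject)"))
  f_null <- if (use_hemi) {
    wpi ~ hemisphere + (1 | subject)
  } else {
    wpi ~ 1 + (1 | subject)
  }
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(f_full, data = dat, REML = TRUE)
  ))
  singular <- lme4::isSingular(fit, tol = 1e-4)
  if (singular) {
    # zero-variance random intercepts: fall back to fixed subject
    # intercepts so the clustering still enters the error model
    ols <- stats::lm(stats::as.formula(paste("wpi ~", fixed, "+ subject")),
                     data = dat)
    co <- summary(ols)$coefficients
    est <- co["feature", "Estimate"]
    se <- co["feature", "Std. Error"]
    p_fixed <- sum(!is.na(coef(ols)))
  } else {
    co <- summary(fit)$coefficients
    est <- co["feature", "Estimate"]
    se <- co["feature", "Std. Error"]
    p_fixed <- nrow(co)
  }
  df <- n - p_fixed
  tval <- est / se
  p_wald <- 2 * stats::pt(-abs(tval), df)
  full_ml <- suppressMessages(suppressWarnings(
    lme4::lmer(f_full, data = dat, REML = FALSE)
  ))
  null_ml <- suppressMessages(suppressWarnings(
    lme4::lmer(f_null, data = dat, REML = FALSE)
  ))
  lrt <- max(0, 2 * (as.numeric(logLik(full_ml)) -
                       as.numeric(logLik(null_ml))))
  p_lrt <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  structure(
    list(estimate = est, se = se, t = tval, df = df, p_wald = p_wald,
         lrt_chisq = lrt, lrt_df = 1L, p_lrt = p_lrt,
         aic = stats::AIC(full_ml), n = n, singular = singular,
         model = fit),
    class = "group_model_result"
  )
}

#' Hemisphere-interaction check for a group feature model
#'
#' Fits the feature x hemisphere interaction model and reports
#' `delta_aic = AIC(interaction) - AIC(main)` (both by maximum
#' likelihood) together with the interaction Wald p-value. A positive
#' delta AIC means the interaction does not improve fit, i.e. the
#' feature's link to WPI is hemisphere-invariant.
#'
#' @inheritParams fit_group_feature_model
#' @return List `delta_aic`, `interaction_p`, or a skipped marker for
#'   unilateral-only data.
#' @export
hemisphere_interaction_check <- function(feature, wpi, subject, hemisphere) {
  dat <- data.frame(wpi = wpi, feature = feature, subject = factor(subject),
                    hemisphere = factor(hemisphere))
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nlevels(droplevels(dat$hemisphere)) < 2L) {
    return(list(skipped = TRUE,
                note = "unilateral-only data; interaction not testable"))
  }
  main <- suppressMessages(suppressWarnings(
    lme4::lmer(wpi ~ feature + hemisphere + (1 | subject), data = dat,
               REML = FALSE)
  ))
  inter <- suppressMessages(suppressWarnings(
    lme4::lmer(wpi ~ feature * hemisphere + (1 | subject), data = dat,
               REML = FALSE)
  ))
  co <- summary(inter)$coefficients
  irow <- grep(":", rownames(co))[1]
  tval <- co[irow, "t value"]
  df <- nrow(dat) - nrow(co)
  list(
    skipped = FALSE,
    delta_aic = stats::AIC(inter) - stats::AIC(main),
    interaction_p = 2 * stats::pt(-abs(tval), df)
  )
}

#' Backward elimination over a set of neural features
#'
#' Starting from a mixed model containing all candidate features as fixed
#' effects (plus a random subject intercept), repeatedly drops the least
#' significant feature by likelihood-ratio test until every remaining
#' feature is significant at `alpha`. Models are compared by maximum
#' likelihood. Elimination down to an empty set returns the
#' intercept-only model's feature list (empty).
#'
#' @param feature_matrix Data frame / matrix of candidate features
#'   (columns named).
#' @param wpi Response per observation.
#' @param subject Subject id per observation.
#' @param alpha Retention threshold (default 0.05).
#' @return Character vector of retained feature names, with a `trace`
#'   attribute recording each elimination step.
#' @export
backward_select <- function(feature_matrix, wpi, subject, alpha = 0.05) {
  fm <- as.data.frame(feature_matrix)
  keep <- stats::complete.cases(fm) & is.finite(wpi)
  fm <- fm[keep, , drop = FALSE]
  dat <- cbind(fm, wpi = wpi[keep], subject = factor(subject[keep]))
  current <- names(fm)
  trace <- character(0)
  fit_with <- function(feats) {
    rhs <- if (length(feats)) paste(feats, collapse = " + ") else "1"
    suppressMessages(suppressWarnings(
      lme4::lmer(stats::as.formula(paste("wpi ~", rhs, "+ (1 | subject)")),
                 data = dat, REML = FALSE)
    ))
  }
  repeat {
    if (length(current) == 0L) break
    full <- fit_with(current)
    pv <- vapply(current, function(f) {
      red <- fit_with(setdiff(current, f))
      lr <- max(0, 2 * (as.numeric(logLik(full)) -
                          as.numeric(logLik(red))))
      stats::pchisq(lr, df = 1, lower.tail = FALSE)
    }, numeric(1))
    worst <- which.max(pv)
    if (pv[worst] > alpha) {
      trace <- c(trace, sprintf("dropped %s (LRT p = %.3g)",
                                current[worst], pv[worst]))
      current <- current[-worst]
    } else {
      break
    }
  }
  structure(current, trace = trace)
}

#' Residual diagnostics for a fitted model
#'
#' Shapiro-Wilk normality test plus sample skewness and Pearson
#' (non-excess) kurtosis of the residuals, with pass flags at
#' configurable thresholds (defaults |skewness| < 0.39 and kurtosis
#' < 3.6, conventional acceptability references for mixed-model
#' residuals).
#'
#' @param model A fitted model (anything `resid()` understands) or a
#'   numeric residual vector.
#' @param skew_threshold,kurt_threshold Acceptability thresholds.
#' @return A `diagnostics_report` data frame row: `shapiro_p`,
#'   `skewness`, `kurtosis`, `skew_ok`, `kurt_ok`, `n`, `descriptive_only`.
#' @export
residual_diagnostics <- function(model, skew_threshold = 0.39,
                                 kurt_threshold = 3.6) {
  r <- if (is.numeric(model)) model else stats::resid(model)
  r <- r[is.finite(r)]
  n <- length(r)
  desc_only <- n < 8L
  sp <- if (!desc_only) stats::shapiro.test(r)$p.value else NA_real_
  sk <- sample_skewness(r)
  ku <- sample_kurtosis(r)
  data.frame(
    shapiro_p = sp, skewness = sk, kurtosis = ku,
    skew_ok = abs(sk) < skew_threshold, kurt_ok = ku < kurt_threshold,
    n = n, descriptive_only = desc_only
  )
}

#' Mixed model linking feedback ranks to WPI ranks
#'
#' `feedback_rank ~ wpi_rank + (1 | subject)`: the ranked WPI values are
#' the fixed effect and the subjective feedback rankings the outcome,
#' with a random intercept per subject to absorb within-subject
#' clustering. A slope of 1 means perfect concordance between objective
#' and subjective rankings.
#'
#' @param wpi_rank Within-visit WPI ranks (1 = best).
#' @param feedback_rank Within-visit feedback ranks (1 = most preferred).
#' @param subject Subject id per observation.
#' @return List `slope`, `se`, `t`, `df`, `p`, `singular`, `n`.
#' @export
feedback_rank_model <- function(wpi_rank, feedback_rank, subject) {
  dat <- data.frame(y = feedback_rank, x = wpi_rank,
                    subject = factor(subject))
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (stats::sd(dat$x) < 1e-12 || stats::sd(dat$y) < 1e-12) {
    stop("constant ranks; feedback model undefined")
  }
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(y ~ x + (1 | subject), data = dat, REML = TRUE)
  ))
  singular <- lme4::isSingular(fit, tol = 1e-4)
  if (singular) {
    ols <- stats::lm(y ~ x, data = dat)
    co <- suppressWarnings(summary(ols)$coefficients)
    est <- co["x", "Estimate"]
    se <- co["x", "Std. Error"]
    p_fixed <- 2L
  } else {
    co <- summary(fit)$coefficients
    est <- co["x", "Estimate"]
    se <- co["x", "Std. Error"]
    p_fixed <- nrow(co)
  }
  df <- nrow(dat) - p_fixed
  tval <- est / se
  p <- if (se < 1e-12) 0 else 2 * stats::pt(-abs(tval), df)
  list(slope = est, se = se, t = tval, df = df, p = p,
       singular = singular, n = nrow(dat))
}
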