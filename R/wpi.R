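WPI_METRICS <- c("stride_velocity", "arm_swing_amplitude",
                 "step_length_cv", "step_time_cv")

#' Normalize trial metrics within a visit
#'
#' Per-visit min-max scaling of the four WPI metrics to [0, 1]. Stride
#' velocity and arm swing are oriented so that higher values mean better
#' performance; the two variability components keep "higher = more
#' variable" (the index formula applies the 1 - x flip). A metric that is
#' constant across the visit carries no information and is set to the
#' uninformative midpoint 0.5 for all trials.
#'
#' @param trial_metrics Data frame with one row per trial of a single
#'   visit; columns `stride_velocity`, `arm_swing_amplitude`,
#'   `step_length_cv`, `step_time_cv` (and optionally `trial_id`).
#' @return Data frame with columns `SV_norm`, `AS_norm`, `VSL_norm`,
#'   `VST_norm` (plus `trial_id` when present) and a `degenerate`
#'   attribute naming constant metrics.
#' @export
normalize_metrics <- function(trial_metrics) {
  if (nrow(trial_metrics) < 2L) {
    stop("normalize_metrics needs >= 2 trials in the visit")
  }
  comp_names <- c(stride_velocity = "SV_norm", arm_swing_amplitude = "AS_norm",
                  step_length_cv = "VSL_norm", step_time_cv = "VST_norm")
  out <- data.frame(row.names = seq_len(nrow(trial_metrics)))
  degenerate <- character(0)
  for (m in WPI_METRICS) {
    x <- trial_metrics[[m]]
    if (is.null(x)) stop("missing metric column: ", m)
    rng <- range(x)
    if (diff(rng) < 1e-12) {
      out[[comp_names[[m]]]] <- rep(0.5, length(x))
      degenerate <- c(degenerate, m)
    } else {
      out[[comp_names[[m]]]] <- (x - rng[1]) / diff(rng)
    }
  }
  if (!is.null(trial_metrics$trial_id)) out$trial_id <- trial_metrics$trial_id
  attr(out, "degenerate") <- degenerate
  out
}

#' Walking Performance Index from normalized components
#'
#' Equal-weight composite of the four normalized gait components:
#' \deqn{WPI = (SV_{norm} + AS_{norm} + (1 - VSL_{norm}) + (1 - VST_{norm})) / 4}
#' so that faster strides, larger arm swing and lower step-length and
#' step-time variability all raise the index. Raw WPI lies in [0, 1].
#'
#' @param components Data frame or list with `SV_norm`, `AS_norm`,
#'   `VSL_norm`, `VST_norm`, each in [0, 1] (vectorized).
#' @return Numeric raw WPI value(s).
#' @examples
#' compute_wpi(list(SV_norm = 0.8, AS_norm = 0.6, VSL_norm = 0.3,
#'                  VST_norm = 0.1)) # 0.75
#' @export
compute_wpi <- function(components) {
  comp <- lapply(c("SV_norm", "AS_norm", "VSL_norm", "VST_norm"),
                 function(nm) {
                   x <- components[[nm]]
                   if (is.null(x)) stop("missing component: ", nm)
                   if (any(x < -1e-9 | x > 1 + 1e-9, na.rm = TRUE)) {
                     stop("component outside [0, 1]: ", nm)
                   }
                   x
                 })
  (comp[[1]] + comp[[2]] + (1 - comp[[3]]) + (1 - comp[[4]])) / 4
}

#' Baseline-normalize WPI scores against the clinical setting
#'
#' Each trial's raw WPI is divided by the raw WPI of the visit's
#' clinically optimized trial, so the clinical setting scores 1 and
#' values above 1 indicate improvement over clinical programming.
#'
#' @param scores Data frame with `trial_id` and `raw` (raw WPI) for one
#'   visit.
#' @param clinical_trial_id Trial id of the clinical-setting trial.
#' @return `scores` with a `baseline_normalized` column added.
#' @export
baseline_normalize <- function(scores, clinical_trial_id) {
  i <- match(clinical_trial_id, scores$trial_id)
  if (is.na(i)) stop("clinical trial not present in visit scores")
  ref <- scores$raw[i]
  if (!is.finite(ref) || ref <= 0) {
    stop("clinical trial raw WPI is zero; visit unusable for baseline ",
         "normalization")
  }
  scores$baseline_normalized <- scores$raw / ref
  scores
}

#' Rank trials within a visit by WPI
#'
#' Rank 1 is the best (highest) WPI. Ties are broken stably by trial
#' order and reported via the `ties` attribute.
#'
#' @param scores Data frame with `trial_id` and a WPI column.
#' @param column Which column to rank on (default `baseline_normalized`
#'   falling back to `raw`).
#' @return `scores` with a `rank` column (permutation of 1..n).
#' @export
rank_trials <- function(scores, column = NULL) {
  if (nrow(scores) < 2L) stop("rank_trials needs >= 2 trials")
  if (is.null(column)) {
    column <- if (!is.null(scores$baseline_normalized)) {
      "baseline_normalized"
    } else {
      "raw"
    }
  }
  x <- scores[[column]]
  ord <- order(-x, seq_along(x))
  r <- integer(length(x))
  r[ord] <- seq_along(x)
  scores$rank <- r
  attr(scores, "ties") <- anyDuplicated(x) > 0L
  scores
}

#' Variance inflation factors for the WPI metrics
#'
#' Regresses each metric on the other three across all trials;
#' VIF = 1 / (1 - R^2). Values below 5 indicate acceptable
#' multicollinearity among the index components.
#'
#' @param metric_table Data frame with >= 5 rows and the four metric
#'   columns.
#' @return Data frame `metric`, `vif`, `infinite` flag (exact collinearity).
#' @export
wpi_vif <- function(metric_table) {
  if (nrow(metric_table) < 5L) stop("VIF needs >= 5 trials")
  X <- as.data.frame(metric_table[, WPI_METRICS])
  out <- lapply(WPI_METRICS, function(m) {
    f <- stats::as.formula(paste(m, "~", paste(setdiff(WPI_METRICS, m),
                                               collapse = " + ")))
    r2 <- suppressWarnings(summary(stats::lm(f, data = X)))$r.squared
    inf <- r2 > 1 - 1e-10
    data.frame(metric = m, vif = if (inf) Inf else 1 / (1 - r2),
               infinite = inf)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' WPI sensitivity to perturbations of each metric
#'
#' Scales each metric by (1 +/- delta) in turn, renormalizes the visit's
#' components and recomputes the WPI; reports the mean change per trial.
#'
#' @param metric_table Per-trial metric table for one visit (>= 2 rows).
#' @param delta Fractional perturbation (default 0.10); must be > -1.
#' @return Data frame `metric`, `direction` (+1/-1), `mean_delta_wpi`,
#'   `max_abs_delta_wpi` (4 metrics x 2 signs = 8 rows).
#' @export
wpi_sensitivity <- function(metric_table, delta = 0.10) {
  if (delta <= -1) stop("delta must be > -1")
  base <- compute_wpi(normalize_metrics(metric_table))
  rows <- list()
  for (m in WPI_METRICS) {
    for (sgn in c(1, -1)) {
      pert <- metric_table
      pert[[m]] <- pert[[m]] * (1 + sgn * delta)
      w <- compute_wpi(normalize_metrics(pert))
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, direction = sgn,
        mean_delta_wpi = mean(w - base),
        max_abs_delta_wpi = max(abs(w - base))
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare stride metrics between two conditions
#'
#' Percent change of the condition means and a Wilcoxon signed-rank test
#' with strides paired by their within-trial order index (sequences are
#' truncated to the shorter condition). With fewer than `min_strides`
#' strides in either condition only descriptive output is returned.
#'
#' @param strides_a,strides_b Data frames of stride metrics
#'   ([compute_stride_metrics()]) for conditions A and B.
#' @param metrics Metric columns to compare.
#' @param min_strides Minimum strides per condition for testing.
#' @return Data frame `metric`, `mean_a`, `mean_b`, `percent_change`
#'   (B vs A), `n_pairs`, `p_value` (NA when descriptive only).
#' @export
compare_conditions <- function(strides_a, strides_b,
                               metrics = c("stride_velocity",
                                           "arm_swing_amplitude",
                                           "step_time_s", "step_length_m"),
                               min_strides = 10) {
  rows <- lapply(metrics, function(m) {
    a <- strides_a[[m]]
    b <- strides_b[[m]]
    n <- min(length(a), length(b))
    pc <- 100 * (mean(b) - mean(a)) / mean(a)
    p <- NA_real_
    if (length(a) >= min_strides && length(b) >= min_strides) {
      d <- b[seq_len(n)] - a[seq_len(n)]
      if (all(d == 0)) {
        p <- 1
      } else {
        p <- suppressWarnings(
          stats::wilcox.test(a[seq_len(n)], b[seq_len(n)],
                             paired = TRUE, exact = FALSE)$p.value
        )
      }
    }
    data.frame(metric = m, mean_a = mean(a), mean_b = mean(b),
               percent_change = pc, n_pairs = n, p_value = p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
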