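#' Matern covariance between stimulation settings
#'
#' Anisotropic Matern kernel
#' \deqn{k(x_i, x_j) = \frac{1}{\Gamma(\nu) 2^{\nu-1}}
#'   (\sqrt{2\nu}\, r)^{\nu} K_\nu(\sqrt{2\nu}\, r)}
#' where r is the Euclidean distance after per-axis division by the
#' length scales and \eqn{K_\nu} is the modified Bessel function of the
#' second kind. For the default smoothness \eqn{\nu = 3/2} this equals
#' the closed form \eqn{(1 + \sqrt{3} r)\exp(-\sqrt{3} r)}.
#'
#' @param x1,x2 Numeric setting vectors (mA, Hz, us) of equal length.
#' @param length_scales Positive per-axis length scales.
#' @param nu Smoothness parameter (> 0), default 1.5.
#' @return Covariance value in (0, 1].
#' @examples
#' matern_cov(c(5, 130, 60), c(5, 130, 60), c(1, 20, 10)) # 1
#' @export
matern_cov <- function(x1, x2, length_scales, nu = 1.5) {
  if (length(x1) != length(x2)) stop("inputs must have equal dimension")
  if (any(length_scales <= 0)) stop("length scales must be positive")
  if (nu <= 0) stop("nu must be positive")
  r <- sqrt(sum(((x1 - x2) / length_scales)^2))
  matern_r(r, nu)
}

matern_r <- function(r, nu) {
  out <- numeric(length(r))
  tiny <- r < 1e-12
  out[tiny] <- 1
  rr <- r[!tiny]
  if (length(rr)) {
    a <- sqrt(2 * nu) * rr
    out[!tiny] <- (2^(1 - nu) / gamma(nu)) * a^nu * besselK(a, nu)
  }
  out
}

# Pairwise Matern kernel matrix between scaled input matrices (rows = points).
matern_kernel_matrix <- function(X1, X2, length_scales, nu) {
  Xs1 <- sweep(X1, 2, length_scales, "/")
  Xs2 <- sweep(X2, 2, length_scales, "/")
  d2 <- outer(rowSums(Xs1^2), rowSums(Xs2^2), "+") - 2 * Xs1 %*% t(Xs2)
  r <- sqrt(pmax(d2, 0))
  matrix(matern_r(as.numeric(r), nu), nrow = nrow(X1))
}

#' Gaussian-process regression configuration
#'
#' Defaults follow the study protocol: Matern smoothness 1.5, initial
#' length scales (1, 20, 10) for amplitude (mA), frequency (Hz) and
#' pulse width (us), and 40 optimizer restarts for the log-marginal
#' likelihood maximization. Inputs are kept in raw physical units so the
#' length scales retain their physical meaning. Observation noise is a
#' fitted hyperparameter; targets are centered before fitting.
#'
#' @param nu Matern smoothness.
#' @param length_scales Initial per-axis length scales.
#' @param length_scale_bounds Two-column matrix (or c(lo, hi) recycled)
#'   of box bounds for the length scales.
#' @param noise_init Initial observation-noise variance.
#' @param noise_bounds Bounds for the noise variance.
#' @param signal_init Initial signal variance.
#' @param signal_bounds Bounds for the signal variance.
#' @param restarts Optimizer restarts (>= 1); restart initializations are
#'   drawn log-uniform within the length-scale bounds from a seeded
#'   stream.
#' @param seed Seed for the restart stream.
#' @return A `gpr_config` list.
#' @export
gpr_config <- function(nu = 1.5, length_scales = c(1, 20, 10),
                       length_scale_bounds = cbind(
                         c(0.05, 1, 0.5), c(50, 1000, 500)
                       ),
                       noise_init = 1e-2, noise_bounds = c(1e-8, 1),
                       signal_init = 0.05, signal_bounds = c(1e-6, 10),
                       restarts = 40, seed = 0) {
  if (restarts < 1) stop("restarts must be >= 1")
  if (any(length_scales <= 0)) stop("length scales must be positive")
  structure(
    list(nu = nu, length_scales = length_scales,
         length_scale_bounds = length_scale_bounds,
         noise_init = noise_init, noise_bounds = noise_bounds,
         signal_init = signal_init, signal_bounds = signal_bounds,
         restarts = restarts, seed = seed),
    class = "gpr_config"
  )
}

# Negative log-marginal likelihood and its gradient in log-parameter space.
# theta = log(c(length_scales, signal_var, noise_var)).
gpr_nlml <- function(theta, X, y, nu) {
  d <- ncol(X)
  ls <- exp(theta[seq_len(d)])
  sf2 <- exp(theta[d + 1])
  sn2 <- exp(theta[d + 2])
  n <- nrow(X)
  K <- sf2 * matern_kernel_matrix(X, X, ls, nu) + diag(sn2, n)
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(list(value = 1e10, gradient = rep(0, d + 2)))
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  nlml <- 0.5 * sum(y * alpha) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)

  Kinv <- chol2inv(ch)
  A <- alpha %*% t(alpha) - Kinv
  Xs <- sweep(X, 2, ls, "/")
  d2 <- outer(rowSums(Xs^2), rowSums(Xs^2), "+") - 2 * Xs %*% t(Xs)
  r <- sqrt(pmax(d2, 0))
  # dK/dr * r, computed stably via the nu=1.5 closed form when applicable
  grad <- numeric(d + 2)
  M <- matern_r(as.numeric(r), nu)
  if (abs(nu - 1.5) < 1e-12) {
    s3r <- sqrt(3) * r
    dM_rdr <- -3 * r^2 * exp(-s3r)    # r * dM/dr
  } else {
    eps <- 1e-6
    dM_rdr <- r * (matern_r(as.numeric(r) + eps, nu) -
                     matern_r(pmax(as.numeric(r) - eps, 0), nu)) / (2 * eps)
    dM_rdr <- matrix(dM_rdr, n, n)
  }
  for (j in seq_len(d)) {
    # d r/d log l_j = -(x_j distance component)^2 / (l_j^2 r)
    diffj <- outer(X[, j], X[, j], "-") / ls[j]
    with_r <- r > 1e-12
    dK <- matrix(0, n, n)
    dK[with_r] <- sf2 * dM_rdr[with_r] * (-(diffj[with_r]^2) / r[with_r]^2)
    grad[j] <- -0.5 * sum(A * dK)
  }
  grad[d + 1] <- -0.5 * sum(A * (sf2 * matrix(M, n, n)))
  grad[d + 2] <- -0.5 * sum(diag(A)) * sn2
  list(value = nlml, gradient = grad)
}

#' Fit a Matern-kernel Gaussian process mapping settings to WPI
#'
#' Hyperparameters (anisotropic length scales, signal variance,
#' observation-noise variance) are chosen by maximizing the log-marginal
#' likelihood with L-BFGS-B in log space, restarted from `restarts`
#' seeded initializations to avoid poor local optima. Targets are
#' centered by their mean, which is restored at prediction.
#'
#' @param settings Matrix (n x 3) or data frame of settings
#'   (amplitude_mA, frequency_Hz, pulse_width_us), or list of
#'   [stim_setting()].
#' @param wpi Numeric targets (typically baseline-normalized WPI).
#' @param config A [gpr_config()].
#' @return A `gpr_model`: training data, optimized hyperparameters and
#'   achieved log-marginal likelihood.
#' @export
fit_gpr <- function(settings, wpi, config = gpr_config()) {
  X <- settings_matrix(settings)
  y <- as.numeric(wpi)
  if (nrow(X) != length(y)) stop("settings and wpi lengths differ")
  if (nrow(X) < 3L) stop("need >= 3 observations")
  if (nrow(unique(X)) < 2L) stop("all settings identical; cannot fit")
  y_mean <- mean(y)
  yc <- y - y_mean
  d <- ncol(X)
  lb <- c(log(config$length_scale_bounds[, 1]), log(config$signal_bounds[1]),
          log(config$noise_bounds[1]))
  ub <- c(log(config$length_scale_bounds[, 2]), log(config$signal_bounds[2]),
          log(config$noise_bounds[2]))
  inits <- list(c(log(config$length_scales), log(config$signal_init),
                  log(config$noise_init)))
  if (config$restarts > 1L) {
    extra <- with_seed(derive_seed(config$seed, "gpr-restarts"), function() {
      lapply(seq_len(config$restarts - 1L), function(i) {
        runif(d + 2, lb, ub)
      })
    })
    inits <- c(inits, extra)
  }
  best <- NULL
  for (init in inits) {
    fit <- tryCatch(
      stats::optim(
        init,
        fn = function(th) gpr_nlml(th, X, yc, config$nu)$value,
        gr = function(th) gpr_nlml(th, X, yc, config$nu)$gradient,
        method = "L-BFGS-B", lower = lb, upper = ub,
        control = list(maxit = 100)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("GPR hyperparameter optimization failed")
  th <- best$par
  ls <- exp(th[seq_len(d)])
  sf2 <- exp(th[d + 1])
  sn2 <- exp(th[d + 2])
  K <- sf2 * matern_kernel_matrix(X, X, ls, config$nu) + diag(sn2, nrow(X))
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), yc))
  structure(
    list(X = X, y = y, y_mean = y_mean, length_scales = ls,
         signal_var = sf2, noise_var = sn2, nu = config$nu,
         log_marginal_likelihood = -best$value, chol = ch, alpha = alpha,
         config = config),
    class = "gpr_model"
  )
}

settings_matrix <- function(settings) {
  if (is.matrix(settings)) return(settings)
  if (is.data.frame(settings)) {
    return(as.matrix(settings[, c("amplitude_mA", "frequency_Hz",
                                  "pulse_width_us")]))
  }
  if (is.list(settings)) {
    return(do.call(rbind, lapply(settings, setting_vec)))
  }
  stop("unsupported settings container")
}

#' @export
print.gpr_model <- function(x, ...) {
  cat(sprintf(
    "<gpr_model> n=%d, length scales (%.3g, %.3g, %.3g), noise var %.3g, LML %.3f\n",
    nrow(x$X), x$length_scales[1], x$length_scales[2], x$length_scales[3],
    x$noise_var, x$log_marginal_likelihood
  ))
  invisible(x)
}

#' Posterior prediction over a settings grid
#'
#' Standard Gaussian-process posterior mean and SD. Far from all
#' training data the prediction reverts to the prior (the training-target
#' mean, with SD equal to the prior signal SD); at a noise-free training
#' point the SD approaches 0.
#'
#' @param object A `gpr_model`.
#' @param newdata Settings matrix / data frame / list (non-empty).
#' @param ... Unused.
#' @return Data frame `mean`, `sd` (one row per requested setting).
#' @export
predict.gpr_model <- function(object, newdata, ...) {
  Xs <- settings_matrix(newdata)
  if (nrow(Xs) == 0L) stop("empty prediction grid")
  Ks <- object$signal_var *
    matern_kernel_matrix(Xs, object$X, object$length_scales, object$nu)
  mu <- as.numeric(Ks %*% object$alpha) + object$y_mean
  V <- forwardsolve(t(object$chol), t(Ks))
  var <- pmax(object$signal_var - colSums(V^2), 0)
  data.frame(mean = mu, sd = sqrt(var))
}

#' Propose best and worst settings from a fitted model
#'
#' Evaluates the posterior mean over a regular grid on the safe box
#' (default device-realistic increments of 0.1 mA, 5 Hz, 10 us) and
#' returns the grid argmax as the predicted-best and the argmin as the
#' predicted-worst setting, with ties broken toward lower amplitude then
#' lower frequency. This pure-exploitation two-tail policy mirrors a
#' protocol that tests the model's best and worst predictions alongside
#' the clinical setting at each visit.
#'
#' @param model A `gpr_model`.
#' @param safe_range Safe parameter box (see [subject_config()]).
#' @param resolution Grid steps `c(mA, Hz, us)`.
#' @param clinical Optional clinical [stim_setting()] passed through.
#' @param exclude Optional matrix/data frame of already-tested settings;
#'   grid points within half a grid step of a tested setting are skipped
#'   when proposing, so repeat visits probe new ground.
#' @return A `settings_proposal` list: `best`, `worst`, `clinical`, and
#'   predicted `mean`/`sd` at each.
#' @export
propose_settings <- function(model, safe_range,
                             resolution = c(0.1, 5, 10), clinical = NULL,
                             exclude = NULL) {
  grid <- setting_grid(safe_range, resolution)
  pred <- predict(model, grid)
  mean_best <- pred$mean
  mean_worst <- pred$mean
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    ex <- settings_matrix(exclude)
    gm <- as.matrix(grid)
    tested <- rep(FALSE, nrow(gm))
    for (i in seq_len(nrow(ex))) {
      hit <- abs(gm[, 1] - ex[i, 1]) <= resolution[1] / 2 &
        abs(gm[, 2] - ex[i, 2]) <= resolution[2] / 2 &
        abs(gm[, 3] - ex[i, 3]) <= resolution[3] / 2
      tested <- tested | hit
    }
    if (!all(tested)) {
      mean_best[tested] <- -Inf
      mean_worst[tested] <- Inf
    }
  }
  i_best <- which.max(mean_best)
  i_worst <- which.min(mean_worst)
  as_setting <- function(i) {
    stim_setting(grid$amplitude_mA[i], grid$frequency_Hz[i],
                 grid$pulse_width_us[i])
  }
  out <- list(
    best = as_setting(i_best), worst = as_setting(i_worst),
    clinical = clinical,
    predicted = data.frame(
      which = c("best", "worst"),
      mean = pred$mean[c(i_best, i_worst)],
      sd = pred$sd[c(i_best, i_worst)]
    )
  )
  if (!is.null(clinical)) {
    pc <- predict(model, list(clinical))
    out$predicted <- rbind(out$predicted,
                           data.frame(which = "clinical", mean = pc$mean,
                                      sd = pc$sd))
  }
  structure(out, class = "settings_proposal")
}

#' Space-filling initial design of stimulation settings
#'
#' A maximin Latin-hypercube sample over the safe box, optionally
#' prepended with the clinical setting — the settings a programming
#' session would test before the model takes over proposals.
#'
#' @param safe_range Safe parameter box.
#' @param n Number of probe settings.
#' @param seed Integer seed.
#' @param clinical Optional clinical [stim_setting()] to prepend.
#' @return List of [stim_setting()].
#' @export
initial_design <- function(safe_range, n = 10, seed = 1, clinical = NULL) {
  safe_range <- check_safe_range(safe_range)
  L <- with_seed(derive_seed(seed, "initial-design"), function() {
    lhs::maximinLHS(n, 3)
  })
  lo <- vapply(safe_range, `[`, numeric(1), 1L)
  hi <- vapply(safe_range, `[`, numeric(1), 2L)
  probes <- lapply(seq_len(n), function(i) {
    v <- lo + L[i, ] * (hi - lo)
    stim_setting(v[1], v[2], v[3])
  })
  if (!is.null(clinical)) probes <- c(list(clinical), probes)
  probes
}

#' Iterative optimization loop over walking trials
#'
#' Emulates the visit-by-visit protocol: fit the model on all observed
#' (setting, WPI) pairs, propose the predicted-best and predicted-worst
#' settings, evaluate them together with the clinical setting through
#' the oracle (a walking-trial evaluation returning observed WPI), append
#' the results and repeat until the evaluation budget is exhausted.
#'
#' @param oracle Function `(stim_setting) -> observed WPI`.
#' @param safe_range Safe parameter box.
#' @param clinical Clinical [stim_setting()].
#' @param initial_settings List of settings for the initial design
#'   (>= 3, typically including `clinical`).
#' @param budget Total number of oracle evaluations allowed.
#' @param config A [gpr_config()].
#' @param resolution Proposal grid resolution.
#' @return An `optimization_history`: data frame `iteration`, setting
#'   columns, `observed_wpi`, `role`, `running_best`, plus the final
#'   model.
#' @export
run_optimization_loop <- function(oracle, safe_range, clinical,
                                  initial_settings, budget = 15,
                                  config = gpr_config(),
                                  resolution = c(0.1, 5, 10)) {
  if (length(initial_settings) < 3L) {
    stop("initial design needs >= 3 settings")
  }
  evals <- list()
  add_eval <- function(setting, iteration, role) {
    w <- tryCatch(oracle(setting), error = function(e) e)
    if (inherits(w, "error")) return(FALSE)
    evals[[length(evals) + 1L]] <<- data.frame(
      iteration = iteration,
      amplitude_mA = setting$amplitude_mA,
      frequency_Hz = setting$frequency_Hz,
      pulse_width_us = setting$pulse_width_us,
      observed_wpi = w, role = role
    )
    TRUE
  }
  aborted <- FALSE
  for (s in initial_settings) {
    if (length(evals) >= budget) break
    if (!add_eval(s, 0L, if (isTRUE(s$clinical)) "clinical" else "initial")) {
      aborted <- TRUE
      break
    }
  }
  model <- NULL
  it <- 0L
  while (!aborted && length(evals) < budget) {
    it <- it + 1L
    hist <- do.call(rbind, evals)
    model <- fit_gpr(hist[, c("amplitude_mA", "frequency_Hz",
                              "pulse_width_us")],
                     hist$observed_wpi, config)
    prop <- propose_settings(model, safe_range, resolution, clinical,
                             exclude = hist[, c("amplitude_mA",
                                                "frequency_Hz",
                                                "pulse_width_us")])
    for (role in c("best", "worst", "clinical")) {
      if (length(evals) >= budget) break
      s <- if (role == "clinical") clinical else prop[[role]]
      if (!add_eval(s, it, role)) {
        aborted <- TRUE
        break
      }
    }
  }
  hist <- do.call(rbind, evals)
  hist$running_best <- cummax(hist$observed_wpi)
  # final model incorporates every observation, including the last round
  if (!is.null(hist) && nrow(hist) >= 3L) {
    model <- tryCatch(
      fit_gpr(hist[, c("amplitude_mA", "frequency_Hz", "pulse_width_us")],
              hist$observed_wpi, config),
      error = function(e) model
    )
  }
  structure(
    list(history = hist, model = model, aborted = aborted,
         final_proposal = if (!is.null(model)) {
           propose_settings(model, safe_range, resolution, clinical)
         } else {
           NULL
         }),
    class = "optimization_history"
  )
}
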