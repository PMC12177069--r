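#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in order — simulate (synthetic cohort),
#' gait (event detection and trial metrics), wpi (index + ranks +
#' VIF/sensitivity), spectral (phase-band features), optimize (GPR loop
#' per subject against the ground-truth surface oracle) and stats
#' (group and per-subject biomarker models, feedback-rank model) —
#' writing each stage's outputs into its own subdirectory of `out_dir`
#' and a provenance manifest with seeds and file hashes. Stages never
#' modify another stage's outputs. A stage failure halts the run with
#' the stage name; earlier outputs are preserved.
#'
#' @param config Configuration list (see [default_pipeline_config()] /
#'   [load_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the key in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("stimgait_run_")) {
  config <- validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  stages <- config$stages
  res <- list()
  log_lines <- character(0)
  say <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...))
    log_lines <<- c(log_lines, line)
  }
  run_stage <- function(name, fn) {
    if (!name %in% stages) return(invisible(NULL))
    say("stage %s: start (seed %d)", name, derive_seed(seed, name))
    ok <- tryCatch({
      fn()
      TRUE
    }, error = function(e) {
      writeLines(c(log_lines, sprintf("stage %s FAILED: %s", name,
                                      conditionMessage(e))),
                 file.path(out_dir, "pipeline.log"))
      stop(sprintf("pipeline halted at stage `%s`: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    say("stage %s: done", name)
    invisible(ok)
  }

  run_stage("simulate", function() {
    d <- file.path(out_dir, "simulate")
    dir.create(d, showWarnings = FALSE)
    cc <- cohort_config(
      subjects = example_subjects()[seq_len(config$cohort$n_subjects)],
      n_visits = config$cohort$n_visits,
      n_settings = config$cohort$n_settings,
      n_strides = config$cohort$n_strides,
      turn_every = config$cohort$turn_every,
      neural = isTRUE(config$cohort$neural)
    )
    res$cohort <<- simulate_cohort(cc, seed = derive_seed(seed, "simulate"))
    res$feedback <<- simulate_feedback(
      res$cohort, concordance = config$feedback$concordance,
      seed = derive_seed(seed, "feedback")
    )
    write_table(res$cohort$manifest, file.path(d, "manifest.csv"))
    write_table(res$feedback, file.path(d, "feedback.csv"))
    gt <- do.call(rbind, lapply(res$cohort$trials, function(tr) {
      data.frame(trial_id = tr$trial_id, w_true = tr$ground_truth$w_true,
                 w_obs = tr$ground_truth$w_obs)
    }))
    write_table(gt, file.path(d, "ground_truth_wpi.csv"))
  })

  run_stage("gait", function() {
    d <- file.path(out_dir, "gait")
    dir.create(d, showWarnings = FALSE)
    res$metrics <<- cohort_gait_metrics(res$cohort)
    write_table(res$metrics, file.path(d, "trial_metrics.csv"))
  })

  run_stage("wpi", function() {
    d <- file.path(out_dir, "wpi")
    dir.create(d, showWarnings = FALSE)
    res$wpi <<- cohort_wpi(res$cohort, metrics = res$metrics)
    write_table(res$wpi, file.path(d, "wpi.csv"))
    usable <- res$metrics[res$metrics$usable, , drop = FALSE]
    if (nrow(usable) >= 5L) {
      write_table(wpi_vif(usable), file.path(d, "vif.csv"))
    }
    first_visit <- usable[usable$visit_id == usable$visit_id[1], ,
                          drop = FALSE]
    if (nrow(first_visit) >= 2L) {
      write_table(wpi_sensitivity(first_visit),
                  file.path(d, "sensitivity.csv"))
    }
  })

  run_stage("spectral", function() {
    d <- file.path(out_dir, "spectral")
    dir.create(d, showWarnings = FALSE)
    feats <- cohort_features(
      res$cohort, sites = config$spectral$sites,
      pairs = config$spectral$pairs, bands = config$spectral$bands,
      fmin = config$spectral$fmin, fmax = config$spectral$fmax
    )
    res$features <<- build_feature_table(feats, res$wpi,
                                         res$cohort$manifest)
    write_table(res$features, file.path(d, "feature_table.csv"))
  })

  run_stage("optimize", function() {
    d <- file.path(out_dir, "optimize")
    dir.create(d, showWarnings = FALSE)
    opt <- list()
    for (subject in res$cohort$subjects) {
      sid <- subject$subject_id
      surf <- res$cohort$surfaces[[sid]]
      oseed <- derive_seed(seed, paste0("optimize:", sid))
      counter <- new.env()
      counter$i <- 0L
      oracle <- function(s) {
        counter$i <- counter$i + 1L
        w <- true_wpi(surf, s)
        with_seed(derive_seed(oseed, paste0("eval", counter$i)),
                  function() w + rnorm(1, 0, surf$observation_noise_sd))
      }
      init <- with_seed(oseed, function() {
        c(list(subject$clinical_setting),
          replicate(3, stim_setting(
            runif(1, subject$safe_range$amplitude_mA[1],
                  subject$safe_range$amplitude_mA[2]),
            runif(1, subject$safe_range$frequency_Hz[1],
                  subject$safe_range$frequency_Hz[2]),
            runif(1, subject$safe_range$pulse_width_us[1],
                  subject$safe_range$pulse_width_us[2])
          ), simplify = FALSE))
      })
      h <- run_optimization_loop(
        oracle, subject$safe_range, subject$clinical_setting, init,
        budget = config$gpr$budget,
        config = gpr_config(restarts = config$gpr$restarts, seed = oseed)
      )
      opt[[sid]] <- h
      write_table(h$history, file.path(d, paste0("history_", sid, ".csv")))
      if (!is.null(h$model)) {
        jsonlite::write_json(
          list(length_scales = h$model$length_scales,
               signal_var = h$model$signal_var,
               noise_var = h$model$noise_var,
               log_marginal_likelihood = h$model$log_marginal_likelihood,
               best = unclass(h$final_proposal$best)[1:3],
               worst = unclass(h$final_proposal$worst)[1:3]),
          file.path(d, paste0("model_", sid, ".json")), auto_unbox = TRUE,
          digits = NA
        )
      }
    }
    res$optimization <<- opt
  })

  run_stage("stats", function() {
    d <- file.path(out_dir, "stats")
    dir.create(d, showWarnings = FALSE)
    ft <- res$features
    group <- list()
    for (band in unique(ft$band)) {
      for (key in unique(ft$site_or_pair)) {
        for (ph in unique(ft$phase)) {
          sub <- ft[ft$band == band & ft$site_or_pair == key &
                      ft$phase == ph, , drop = FALSE]
          sub <- sub[is.finite(sub$value) & is.finite(sub$wpi), ,
                     drop = FALSE]
          if (nrow(sub) < 20L ||
              length(unique(sub$subject_id)) < 3L) next
          gm <- fit_group_feature_model(sub$value, sub$wpi,
                                        sub$subject_id, sub$hemisphere)
          group[[length(group) + 1L]] <- data.frame(
            site_or_pair = key, band = band, phase = ph,
            estimate = gm$estimate, se = gm$se, t = gm$t, df = gm$df,
            p_wald = gm$p_wald, lrt_chisq = gm$lrt_chisq,
            p_lrt = gm$p_lrt, n = gm$n, singular = gm$singular
          )
        }
      }
    }
    if (length(group)) {
      gdf <- do.call(rbind, group)
      gdf$p_lrt_adjusted <- bh_adjust(gdf$p_lrt)
      res$group_models <<- gdf
      write_table(gdf, file.path(d, "group_models.csv"))
    }
    subj <- fit_subject_phase_models(ft[ft$kind == "power", , drop = FALSE])
    if (nrow(subj)) {
      res$subject_models <<- subj
      write_table(subj, file.path(d, "subject_models.csv"))
    }
    fb <- merge(res$feedback,
                res$wpi[, c("trial_id", "rank")], by = "trial_id")
    fm <- feedback_rank_model(fb$rank, fb$feedback_rank, fb$subject_id)
    res$feedback_model <<- fm
    jsonlite::write_json(fm[c("slope", "se", "t", "df", "p", "n")],
                         file.path(d, "feedback_model.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  # the manifest itself and the timestamped log are not content outputs
  files <- setdiff(files, file.path(out_dir, c("manifest.json",
                                               "pipeline.log")))
  manifest <- list(
    package_version = as.character(utils::packageVersion("stimgait")),
    seed = seed, stages = stages,
    files = lapply(files, function(f) {
      list(path = sub(paste0("^", out_dir, "/?"), "", f),
           md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  res$manifest <- manifest
  res$out_dir <- out_dir
  invisible(res)
}
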