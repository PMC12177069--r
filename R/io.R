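#' Write / read a tabular result file
#'
#' CSV round-trip helpers used by every stage. Numeric payloads are
#' written at 15 significant digits, the declared precision for lossless
#' round-trips; missing values are preserved as empty fields.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `write_table` the path invisibly; `read_table` a data frame.
#' @export
write_table <- function(x, path) {
  num <- vapply(x, is.numeric, logical(1))
  for (j in which(num)) {
    na <- is.na(x[[j]])
    x[[j]] <- trimws(formatC(x[[j]], digits = 15, format = "g"))
    x[[j]][na] <- NA
  }
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read multichannel signals
#'
#' Signals are stored as a float32 column binary (channels interleaved
#' column-wise) with a JSON sidecar recording channel names, sampling
#' rate and length. NaN encodes missing samples and is restored as NA.
#'
#' @param signals Named list of equal-length numeric vectors.
#' @param rate Sampling rate (Hz).
#' @param path Output path for the binary; the sidecar is `path` +
#'   `.json`.
#' @return `write_signals` the path invisibly; `read_signals` a list
#'   with `signals` (named list) and `rate_Hz`.
#' @export
write_signals <- function(signals, rate, path) {
  n <- unique(vapply(signals, length, integer(1)))
  if (length(n) != 1L) stop("all channels must share one length")
  con <- file(path, "wb")
  on.exit(close(con))
  for (ch in names(signals)) {
    v <- signals[[ch]]
    v[is.na(v)] <- NaN
    writeBin(as.numeric(v), con, size = 4)
  }
  jsonlite::write_json(
    list(channels = names(signals), rate_Hz = rate, n_samples = n,
         dtype = "float32"),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_signals
#' @export
read_signals <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  out <- list()
  for (ch in meta$channels) {
    v <- readBin(con, "numeric", n = meta$n_samples, size = 4)
    v[is.nan(v)] <- NA
    out[[ch]] <- v
  }
  list(signals = out, rate_Hz = meta$rate_Hz)
}

#' Default pipeline configuration
#'
#' All tunable parameters of the end-to-end pipeline with their
#' defaults; see the packaged schema
#' (`system.file("extdata", "pipeline-config-schema.json", package =
#' "stimgait")`) for field documentation.
#'
#' @return Named list.
#' @export
default_pipeline_config <- function() {
  list(
    cohort = list(n_subjects = 3, n_visits = 2, n_settings = 3,
                  n_strides = 12, turn_every = 5, neural = TRUE),
    stages = c("simulate", "gait", "wpi", "spectral", "optimize", "stats"),
    spectral = list(sites = c("GP"), pairs = character(0),
                    bands = c("beta"), fmin = 4, fmax = 30),
    gpr = list(budget = 12, restarts = 10),
    feedback = list(concordance = 0.8),
    seed = 1
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a JSON configuration, merges it over the defaults and validates
#' types and ranges, naming the offending field on failure.
#'
#' @param path JSON file path, or NULL for defaults.
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg <- utils::modifyList(cfg, user)
  }
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) stop(sprintf("config field `%s` invalid: %s", field, msg),
                  call. = FALSE)
  }
  chk(is.numeric(cfg$cohort$n_subjects) && cfg$cohort$n_subjects >= 1 &&
        cfg$cohort$n_subjects <= 3, "cohort.n_subjects", "must be 1..3")
  chk(is.numeric(cfg$cohort$n_visits) && cfg$cohort$n_visits >= 1,
      "cohort.n_visits", "must be >= 1")
  chk(is.numeric(cfg$cohort$n_settings) && cfg$cohort$n_settings >= 2,
      "cohort.n_settings", "must be >= 2")
  chk(is.numeric(cfg$cohort$n_strides) && cfg$cohort$n_strides >= 4,
      "cohort.n_strides", "must be >= 4")
  chk(all(cfg$stages %in% c("simulate", "gait", "wpi", "spectral",
                            "optimize", "stats")),
      "stages", "unknown stage name")
  chk(is.numeric(cfg$gpr$budget) && cfg$gpr$budget >= 3,
      "gpr.budget", "must be >= 3")
  chk(is.numeric(cfg$feedback$concordance) &&
        cfg$feedback$concordance >= 0 && cfg$feedback$concordance <= 1,
      "feedback.concordance", "must lie in [0, 1]")
  chk(is.numeric(cfg$seed) && abs(cfg$seed) < 2^31, "seed",
      "must be an integer below 2^31")
  cfg
}
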