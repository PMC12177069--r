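#' Canonical low-frequency band definitions
#'
#' Non-overlapping analysis bands: delta [2, 4), theta [4, 8),
#' alpha [8, 12) and beta [12, 30) Hz. The lower bound is inclusive and
#' the upper bound exclusive, so a grid frequency of exactly 12 Hz
#' belongs to beta, not alpha. Together the bands tile [2, 30).
#'
#' @return Named list of `c(lower, upper)` ranges in Hz.
#' @export
canonical_bands <- function() {
  list(delta = c(2, 4), theta = c(4, 8), alpha = c(8, 12), beta = c(12, 30))
}

GAIT_PHASES <- c("DS1", "CLS", "DS2", "ILS")

# Analytic Morlet wavelet transform of one contiguous segment.
# Unit peak frequency-domain gain: a sinusoid of amplitude A gives |W| = A
# on the ridge.
cwt_segment <- function(x, rate, freqs, omega0 = 6) {
  n <- length(x)
  nfft <- stats::nextn(2 * n, 2)
  X <- fft(c(x, rep(0, nfft - n)))
  w <- 2 * pi * (0:(nfft - 1)) / nfft * rate
  w[w > pi * rate] <- w[w > pi * rate] - 2 * pi * rate
  out <- matrix(0i, nrow = length(freqs), ncol = n)
  for (i in seq_along(freqs)) {
    s <- omega0 / (2 * pi * freqs[i])
    H <- ifelse(w > 0, 2 * exp(-0.5 * (s * w - omega0)^2), 0)
    y <- fft(X * H, inverse = TRUE) / nfft
    out[i, ] <- y[seq_len(n)]
  }
  out
}

# Complex CWT with NA handling: contiguous non-NA segments of at least
# `min_seg_s` are transformed independently; edge columns within one
# wavelet e-folding time (1/f) of a segment boundary are set NA per row.
cwt_complex <- function(x, rate, fmin, fmax, voices = 10, omega0 = 6,
                        min_seg_s = 2) {
  n_oct <- log2(fmax / fmin)
  freqs <- fmin * 2^(seq(0, n_oct, by = 1 / voices))
  freqs <- freqs[freqs <= fmax + 1e-9]
  n <- length(x)
  W <- matrix(NA_complex_, nrow = length(freqs), ncol = n)
  ok <- !is.na(x)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  any_seg <- FALSE
  for (i in seq_along(r$values)) {
    if (!r$values[i] || r$lengths[i] < min_seg_s * rate) next
    any_seg <- TRUE
    seg <- starts[i]:ends[i]
    Wseg <- cwt_segment(x[seg], rate, freqs, omega0)
    for (k in seq_along(freqs)) {
      m <- ceiling(rate / freqs[k])
      len <- length(seg)
      if (2 * m >= len) {
        Wseg[k, ] <- NA_complex_
      } else {
        Wseg[k, c(seq_len(m), (len - m + 1):len)] <- NA_complex_
      }
    }
    W[, seg] <- Wseg
  }
  if (!any_seg) W <- W[, 0, drop = FALSE]
  list(W = W, freq_Hz = freqs)
}

new_tf_map <- function(kind, values, freqs, rate, normalization = "raw") {
  structure(
    list(kind = kind, values = values, freq_Hz = freqs,
         time_s = (seq_len(ncol(values)) - 1) / rate, rate_Hz = rate,
         normalization = normalization),
    class = "tf_map"
  )
}

#' Continuous-wavelet-transform power map
#'
#' Analytic Morlet scalogram |W|^2 on a logarithmic frequency grid
#' (default 10 voices per octave). Missing input samples yield missing
#' columns, with a cone-of-influence-style margin of one wavelet
#' e-folding time per frequency at every segment boundary.
#'
#' @param x Signal (may contain NA from blanking).
#' @param rate Sampling rate (Hz).
#' @param fmin,fmax Frequency range; the primary analyses use 1-30 Hz.
#' @param voices Voices per octave.
#' @param omega0 Morlet center frequency parameter (default 6).
#' @return A `tf_map` with `kind = "power"`.
#' @export
cwt_power <- function(x, rate, fmin = 1, fmax = 30, voices = 10,
                      omega0 = 6) {
  cc <- cwt_complex(x, rate, fmin, fmax, voices, omega0)
  if (ncol(cc$W) == 0L) {
    return(new_tf_map("power", matrix(numeric(0), nrow = length(cc$freq_Hz),
                                      ncol = 0), cc$freq_Hz, rate))
  }
  new_tf_map("power", Mod(cc$W)^2, cc$freq_Hz, rate)
}

# NA-aware moving-average smoothing along rows (time); window in samples.
smooth_time <- function(M, win) {
  if (win <= 1) return(M)
  k <- rep(1, win)
  t(apply(M, 1, function(row) {
    ok <- !is.na(row)
    v <- row
    v[!ok] <- 0
    num <- stats::filter(v, k, sides = 2)
    den <- stats::filter(as.numeric(ok), k, sides = 2)
    out <- as.numeric(num) / as.numeric(den)
    out[den == 0 | is.na(den)] <- NA
    out
  }))
}

# NA-aware boxcar smoothing across scales (rows); width in rows.
smooth_scale <- function(M, width) {
  if (width <= 1) return(M)
  nr <- nrow(M)
  out <- M
  half <- floor(width / 2)
  for (i in seq_len(nr)) {
    rows <- max(1, i - half):min(nr, i + half)
    out[i, ] <- colMeans(M[rows, , drop = FALSE], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA
  out
}

#' Magnitude-squared wavelet coherence
#'
#' Wavelet cross-spectrum smoothed in time (window proportional to the
#' scale period, default 2 cycles) and across scales (boxcar over 0.6
#' octave), normalized by the smoothed auto-spectra and clipped to
#' [0, 1]. Tracks time-varying cortico-pallidal coupling that stationary
#' coherence estimators cannot resolve during gait.
#'
#' @param x,y Signals on a common timeline (NA allowed).
#' @param rate Sampling rate (Hz).
#' @param fmin,fmax,voices,omega0 As in [cwt_power()].
#' @param time_cycles Time-smoothing window in cycles of each scale.
#' @param scale_octaves Scale-smoothing span in octaves.
#' @return A `tf_map` with `kind = "coherence"`, values in [0, 1].
#' @export
wavelet_coherence <- function(x, y, rate, fmin = 1, fmax = 30, voices = 10,
                              omega0 = 6, time_cycles = 2,
                              scale_octaves = 0.6) {
  if (length(x) != length(y)) stop("x and y must share a timeline")
  cx <- cwt_complex(x, rate, fmin, fmax, voices, omega0)
  cy <- cwt_complex(y, rate, fmin, fmax, voices, omega0)
  wcoh_core(cx, cy, rate, voices, time_cycles, scale_octaves)
}

# Coherence from precomputed complex CWTs (shared by wavelet_coherence and
# the cohort feature extractor, which caches per-site transforms).
wcoh_core <- function(cx, cy, rate, voices = 10, time_cycles = 2,
                      scale_octaves = 0.6) {
  if (ncol(cx$W) == 0L || ncol(cy$W) == 0L) {
    return(new_tf_map("coherence",
                      matrix(numeric(0), nrow = length(cx$freq_Hz), ncol = 0),
                      cx$freq_Hz, rate))
  }
  Sxy_re <- matrix(NA_real_, nrow(cx$W), ncol(cx$W))
  Sxy_im <- Sxy_re
  Sxx <- Sxy_re
  Syy <- Sxy_re
  cross <- cx$W * Conj(cy$W)
  for (i in seq_along(cx$freq_Hz)) {
    win <- max(1L, round(time_cycles * rate / cx$freq_Hz[i]))
    Sxy_re[i, ] <- smooth_time(matrix(Re(cross[i, ]), 1), win)
    Sxy_im[i, ] <- smooth_time(matrix(Im(cross[i, ]), 1), win)
    Sxx[i, ] <- smooth_time(matrix(Mod(cx$W[i, ])^2, 1), win)
    Syy[i, ] <- smooth_time(matrix(Mod(cy$W[i, ])^2, 1), win)
  }
  width <- max(1L, round(scale_octaves * voices))
  Sxy_re <- smooth_scale(Sxy_re, width)
  Sxy_im <- smooth_scale(Sxy_im, width)
  Sxx <- smooth_scale(Sxx, width)
  Syy <- smooth_scale(Syy, width)
  coh <- (Sxy_re^2 + Sxy_im^2) / (Sxx * Syy)
  coh <- pmin(pmax(coh, 0), 1)
  new_tf_map("coherence", coh, cx$freq_Hz, rate)
}

#' z-score time-frequency maps per frequency within a visit
#'
#' For each frequency row, subtracts the mean and divides by the SD
#' computed over all non-missing samples pooled across the visit's maps
#' (power and coherence are normalized separately by passing the
#' corresponding maps). A constant row is set to zero and flagged.
#'
#' @param maps List of `tf_map` objects sharing one frequency grid.
#' @return List of normalized maps (`normalization = "z_per_frequency"`),
#'   with a `constant_rows` attribute of flagged frequencies.
#' @export
zscore_per_frequency <- function(maps) {
  if (length(maps) == 0L) stop("no maps supplied")
  freqs <- maps[[1]]$freq_Hz
  nf <- length(freqs)
  mu <- numeric(nf)
  sg <- numeric(nf)
  for (i in seq_len(nf)) {
    vals <- unlist(lapply(maps, function(m) m$values[i, ]))
    vals <- vals[is.finite(vals)]
    mu[i] <- if (length(vals)) mean(vals) else NA_real_
    sg[i] <- if (length(vals) > 1) stats::sd(vals) else 0
  }
  const <- which(!is.na(sg) & sg < 1e-12)
  out <- lapply(maps, function(m) {
    v <- m$values
    for (i in seq_len(nf)) {
      v[i, ] <- if (i %in% const || !is.finite(sg[i]) || sg[i] == 0) {
        ifelse(is.na(v[i, ]), NA_real_, 0)
      } else {
        (v[i, ] - mu[i]) / sg[i]
      }
    }
    m$values <- v
    m$normalization <- "z_per_frequency"
    m
  })
  attr(out, "constant_rows") <- freqs[const]
  out
}

#' Average a time-frequency map over a canonical band
#'
#' Unweighted, missing-aware mean over grid frequencies f with
#' `lower <= f < upper`.
#'
#' @param map A `tf_map`.
#' @param band Band name (see [canonical_bands()]) or `c(lower, upper)`.
#' @return Numeric band time series (NA where all rows are missing).
#' @export
band_average <- function(map, band) {
  label <- if (is.character(band)) band else {
    sprintf("[%g, %g)", band[1], band[2])
  }
  rng <- if (is.character(band)) {
    b <- canonical_bands()[[band]]
    if (is.null(b)) stop("unknown band: ", band)
    b
  } else {
    band
  }
  rows <- which(map$freq_Hz >= rng[1] - 1e-9 & map$freq_Hz < rng[2] - 1e-9)
  if (length(rows) == 0L) {
    stop(sprintf("no grid frequency falls in band %s [%g, %g)", label,
                 rng[1], rng[2]))
  }
  out <- colMeans(map$values[rows, , drop = FALSE], na.rm = TRUE)
  out[is.nan(out)] <- NA
  out
}

#' Per-gait-phase averages of a band time series
#'
#' Means of non-missing samples within each phase interval of each cycle;
#' a phase with more than `max_missing` missing samples is itself set
#' missing. Per-trial features are means over usable (non-turn) cycles.
#'
#' @param series Band time series (from [band_average()]).
#' @param rate Sampling rate of the series (Hz).
#' @param cycles Cycles on the series' timeline (device clock).
#' @param max_missing Maximum tolerated missing fraction per phase.
#' @return List with `per_cycle` (cycle_index, phase, value, stride_time_s)
#'   and `per_trial` (named DS1/CLS/DS2/ILS means over non-turn cycles).
#' @export
phase_average <- function(series, rate, cycles, max_missing = 0.5) {
  bounds <- list(DS1 = c("lhs", "rto"), CLS = c("rto", "rhs"),
                 DS2 = c("rhs", "lto"), ILS = c("lto", "lhs_next"))
  rows <- list()
  for (i in seq_len(nrow(cycles))) {
    cy <- cycles[i, ]
    for (ph in GAIT_PHASES) {
      a <- cy[[bounds[[ph]][1]]]
      b <- cy[[bounds[[ph]][2]]]
      i0 <- max(1L, floor(a * rate) + 1L)
      i1 <- min(length(series), ceiling(b * rate))
      val <- NA_real_
      if (i1 >= i0) {
        seg <- series[i0:i1]
        if (mean(is.na(seg)) <= max_missing && any(!is.na(seg))) {
          val <- mean(seg, na.rm = TRUE)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cycle_index = cy$cycle_index, phase = ph, value = val,
        stride_time_s = cy$stride_time_s, is_turn = cy$is_turn
      )
    }
  }
  per_cycle <- do.call(rbind, rows)
  usable <- per_cycle[!per_cycle$is_turn, , drop = FALSE]
  per_trial <- vapply(GAIT_PHASES, function(ph) {
    v <- usable$value[usable$phase == ph]
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  list(per_cycle = per_cycle, per_trial = per_trial)
}

#' Sort cycles (or per-cycle features) by stride time
#'
#' Ascending stride-time permutation with stable ties, as used to order
#' single-cycle spectrogram rows in phase-locked displays.
#'
#' @param stride_times Numeric stride times.
#' @return Integer permutation.
#' @export
sort_by_stride_time <- function(stride_times) {
  order(stride_times)
}
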