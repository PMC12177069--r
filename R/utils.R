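#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rexp sd var median quantile lm coef anova
#'   AIC complete.cases cor fft nextn optim p.adjust pnorm predict qnorm
#'   shapiro.test approx kruskal.test wilcox.test as.formula logLik pchisq
#'   setNames resid fitted na.omit mvfft aggregate pt cor.test
#' @importFrom utils head tail read.csv write.csv modifyList
NULL

# Derive a reproducible child seed from a parent seed and a string tag.
# Keeps results below 2^31 so they are valid R integer seeds.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 69069 + h * 7919 + 1) %% 2147483647)
}

# Evaluate fn under a local RNG state seeded with `seed`; restores the
# caller's RNG stream afterwards.
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  fn()
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
}

# Merge half-open intervals [start, end); rows with start >= end dropped.
merge_intervals <- function(ints, gap = 0) {
  if (is.null(ints) || nrow(ints) == 0L) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  ints <- ints[order(ints$start), , drop = FALSE]
  out_s <- ints$start[1]
  out_e <- ints$end[1]
  if (nrow(ints) > 1L) {
    for (i in 2:nrow(ints)) {
      if (ints$start[i] <= out_e[length(out_e)] + gap) {
        out_e[length(out_e)] <- max(out_e[length(out_e)], ints$end[i])
      } else {
        out_s <- c(out_s, ints$start[i])
        out_e <- c(out_e, ints$end[i])
      }
    }
  }
  data.frame(start = out_s, end = out_e)
}

# Total overlap (seconds) between one interval [a, b) and a set of intervals.
interval_overlap <- function(a, b, ints) {
  if (is.null(ints) || nrow(ints) == 0L) return(0)
  sum(pmax(0, pmin(b, ints$end) - pmax(a, ints$start)))
}

# Boolean per-sample mask (length n at rate `rate`, t0 = 0) from intervals.
intervals_to_mask <- function(ints, n, rate) {
  mask <- logical(n)
  if (is.null(ints) || nrow(ints) == 0L) return(mask)
  for (i in seq_len(nrow(ints))) {
    i0 <- max(1L, floor(ints$start[i] * rate) + 1L)
    i1 <- min(n, ceiling(ints$end[i] * rate))
    if (i1 >= i0) mask[i0:i1] <- TRUE
  }
  mask
}

# Runs of TRUE in a logical vector -> half-open sample-index intervals.
mask_to_intervals <- function(mask, rate) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(
    start = (starts[keep] - 1L) / rate,
    end = ends[keep] / rate
  )
}

# Sample skewness (g1) and Pearson (non-excess) kurtosis (b2 = m4/m2^2).
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m3 / m2^1.5
}

sample_kurtosis <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m4 <- mean((x - m)^4)
  m4 / m2^2
}

# Coefficient of variation with sample SD (ddof = 1).
cv <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / mean(x)
}
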