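# Internal numerical helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. All generators route their randomness through this.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(code)
}

# Savitzky-Golay smoothing, quadratic fit over a centred odd window.
# Endpoints keep the raw values (windows shrink would complicate the
# translation-invariance property for no benefit at these trace lengths).
sg_smooth <- function(x, window = 5L) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  if (length(x) <= window) return(x)
  m <- (window - 1L) / 2L
  k <- -m:m
  # quadratic least-squares smoothing weights
  A <- cbind(1, k, k^2)
  w <- (A %*% solve(crossprod(A)))[, 1L]
  y <- as.numeric(stats::filter(x, rev(w), sides = 2L))
  y[seq_len(m)] <- x[seq_len(m)]
  n <- length(x)
  y[(n - m + 1L):n] <- x[(n - m + 1L):n]
  y
}

# Central-difference derivative of an SG-smoothed signal, in units per second.
smoothed_derivative <- function(x, rate_hz, window = 5L) {
  s <- sg_smooth(x, window)
  n <- length(s)
  d <- numeric(n)
  d[2:(n - 1L)] <- (s[3:n] - s[1:(n - 2L)]) * rate_hz / 2
  d[1L] <- (s[2L] - s[1L]) * rate_hz
  d[n] <- (s[n] - s[n - 1L]) * rate_hz
  d
}

# Local maxima (strict rises into and falls out of a plateau-free peak)
# with a minimum separation in samples; returns indices.
local_maxima <- function(x, min_sep = 1L) {
  n <- length(x)
  if (n < 3L) return(integer())
  idx <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  if (!length(idx)) return(integer())
  if (min_sep > 1L && length(idx) > 1L) {
    keep <- integer()
    last <- -Inf
    for (i in idx[order(-x[idx])]) {        # highest first
      if (all(abs(i - keep) >= min_sep)) keep <- c(keep, i)
    }
    idx <- sort(keep)
  }
  idx
}

# Topographic prominence of peaks `idx` in `x`: height above the higher of
# the two key cols, where each col is the minimum between the peak and the
# nearest higher ground on that side (or the boundary).
peak_prominences <- function(x, idx) {
  n <- length(x)
  vapply(idx, function(i) {
    h <- x[i]
    lmin <- h
    j <- i - 1L
    while (j >= 1L && x[j] <= h) {
      if (x[j] < lmin) lmin <- x[j]
      j <- j - 1L
    }
    rmin <- h
    j <- i + 1L
    while (j <= n && x[j] <= h) {
      if (x[j] < rmin) rmin <- x[j]
      j <- j + 1L
    }
    h - max(lmin, rmin)
  }, numeric(1))
}

# Linear-interpolated time at which a falling segment first crosses `level`.
# `i` is the first index at/below level; returns time offset in samples
# relative to index 1 of `x` (fractional).
falling_cross <- function(x, i, level) {
  if (i <= 1L) return(i - 1)
  x0 <- x[i - 1L]; x1 <- x[i]
  if (x0 == x1) return(i - 1)
  (i - 2L) + (x0 - level) / (x0 - x1)
}

# Parabolic refinement of an extremum index on a sampled curve; returns a
# fractional index (1-based).
refine_extremum <- function(x, i) {
  n <- length(x)
  if (i <= 1L || i >= n) return(as.numeric(i))
  y0 <- x[i - 1L]; y1 <- x[i]; y2 <- x[i + 1L]
  den <- y0 - 2 * y1 + y2
  if (den == 0) return(as.numeric(i))
  i + 0.5 * (y0 - y2) / den
}

# Sample standard deviation helper retained for clarity: all reported SDs
# in this package use the n-1 denominator.
sample_sd <- function(x) stats::sd(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
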