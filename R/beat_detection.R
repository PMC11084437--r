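#' Detect beats in an intracellular action-potential trace
#'
#' A beat is the local maximum following each upward crossing of
#' `threshold_mv`; successive beats are separated by at least
#' `refractory_s`. The default 0 mV threshold targets overshooting action
#' potentials; lower it for non-overshooting cells. Detection is
#' deterministic and invariant to time shifts.
#'
#' @param trace A [voltage_trace()] with modality `"ap"`.
#' @param threshold_mv Upward crossing threshold (mV).
#' @param refractory_s Minimum separation between detected beats (s).
#' @return A [beat_series()]; empty (0 beats) if the trace never crosses
#'   the threshold.
#' @export
detect_ap_beats <- function(trace, threshold_mv = 0, refractory_s = 0.2) {
  stopifnot(inherits(trace, "voltage_trace"))
  if (trace$modality != "ap") stop("detect_ap_beats expects an 'ap' trace")
  v <- trace$samples
  n <- length(v)
  up <- which(v[-n] < threshold_mv & v[-1L] >= threshold_mv)
  if (!length(up))
    return(beat_series(numeric(), "ap", duration_s = trace_duration(trace)))
  peaks <- integer(length(up))
  for (k in seq_along(up)) {
    i <- up[k] + 1L
    # walk forward while above threshold, take the maximum of that run
    j <- i
    while (j < n && v[j + 1L] >= threshold_mv) j <- j + 1L
    peaks[k] <- i - 1L + which.max(v[i:j])
  }
  peaks <- unique(peaks)
  tms <- trace$t0_s + (peaks - 1L) / trace$rate_hz
  keep <- rep(TRUE, length(tms))
  last <- -Inf
  for (k in seq_along(tms)) {
    if (tms[k] - last < refractory_s) keep[k] <- FALSE else last <- tms[k]
  }
  beat_series(tms[keep], "ap", duration_s = trace_duration(trace))
}

# One-pole RC high-pass; removes field-potential baseline wander without
# ringing. Deterministic, O(n).
rc_highpass <- function(x, rate_hz, corner_hz = 1) {
  a <- 1 / (1 + 2 * pi * corner_hz / rate_hz)
  y <- numeric(length(x))
  y[1L] <- 0
  dx <- diff(x)
  for (i in 2:length(x)) y[i] <- a * (y[i - 1L] + dx[i - 1L])
  y
}

#' Detect spikes in an extracellular microelectrode-array electrogram
#'
#' The trace is detrended with a 1 Hz one-pole high-pass; the noise scale
#' is the scaled median absolute deviation (1.4826 * MAD); samples with
#' `|signal| > k_mad * noise` form supra-threshold runs and the spike time
#' is the absolute extremum within each run. Polarity-invariant.
#'
#' @param trace A [voltage_trace()] with modality `"mea"`, >= 1 s long.
#' @param k_mad Detection threshold in robust-noise units.
#' @param refractory_s Minimum spike separation (s).
#' @return A [beat_series()].
#' @export
detect_mea_spikes <- function(trace, k_mad = 5, refractory_s = 0.1) {
  stopifnot(inherits(trace, "voltage_trace"))
  if (trace$modality != "mea") stop("detect_mea_spikes expects an 'mea' trace")
  if (trace_duration(trace) < 1) stop("trace shorter than 1 s")
  y <- rc_highpass(trace$samples, trace$rate_hz, 1)
  noise <- stats::mad(y)                       # 1.4826 * median |y - med|
  if (noise == 0) noise <- .Machine$double.eps
  over <- abs(y) > k_mad * noise
  if (!any(over))
    return(beat_series(numeric(), "mea", duration_s = trace_duration(trace)))
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  gap <- round(refractory_s * trace$rate_hz)
  # merge runs separated by less than the refractory gap
  idx <- integer()
  k <- 1L
  while (k <= length(runs)) {
    s <- starts[runs[k]]; e <- ends[runs[k]]
    while (k < length(runs) && starts[runs[k + 1L]] - e <= gap) {
      k <- k + 1L
      e <- ends[runs[k]]
    }
    idx <- c(idx, s - 1L + which.max(abs(y[s:e])))
    k <- k + 1L
  }
  tms <- trace$t0_s + (idx - 1L) / trace$rate_hz
  beat_series(tms, "mea", duration_s = trace_duration(trace))
}

#' Detect R-peaks in an ECG trace
#'
#' Band-pass (5-40 Hz Butterworth, zero-phase), differentiate, square and
#' integrate over a 30 ms moving window; runs above an adaptive threshold
#' (a fraction of the upper-percentile integrated energy) mark QRS
#' complexes, and each R time is the absolute extremum of the band-passed
#' signal within the run. Deterministic.
#'
#' @param trace A [voltage_trace()] with modality `"ecg"` sampled at
#'   >= 100 Hz.
#' @param threshold_frac Threshold as a fraction of the 99th percentile of
#'   the integrated energy signal.
#' @param refractory_s Minimum R-R separation (s).
#' @return A [beat_series()].
#' @export
detect_r_peaks <- function(trace, threshold_frac = 0.2, refractory_s = 0.05) {
  stopifnot(inherits(trace, "voltage_trace"))
  if (trace$modality != "ecg") stop("detect_r_peaks expects an 'ecg' trace")
  fs <- trace$rate_hz
  if (fs < 100) stop("rate_hz < 100: insufficient bandwidth for QRS detection")
  v <- trace$samples
  ny <- fs / 2
  bf <- signal::butter(2, c(5, min(40, 0.9 * ny)) / ny, type = "pass")
  bp <- as.numeric(signal::filtfilt(bf, v - mean(v)))
  d <- c(0, diff(bp)) * fs
  en <- d^2
  w <- max(3L, round(0.03 * fs))
  integ <- as.numeric(stats::filter(en, rep(1 / w, w), sides = 2L))
  integ[is.na(integ)] <- 0
  thr <- threshold_frac * stats::quantile(integ, 0.99, names = FALSE)
  if (thr <= 0)
    return(beat_series(numeric(), "ecg", duration_s = trace_duration(trace)))
  over <- integ > thr
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  idx <- integer(length(runs))
  pad <- round(0.01 * fs)
  for (k in seq_along(runs)) {
    s <- max(1L, starts[runs[k]] - pad)
    e <- min(length(bp), ends[runs[k]] + pad)
    idx[k] <- s - 1L + which.max(abs(bp[s:e]))
  }
  idx <- sort(unique(idx))
  tms <- trace$t0_s + (idx - 1L) / fs
  keep <- rep(TRUE, length(tms))
  last <- -Inf
  for (k in seq_along(tms)) {
    if (tms[k] - last < refractory_s) keep[k] <- FALSE else last <- tms[k]
  }
  beat_series(tms[keep], "ecg", duration_s = trace_duration(trace))
}
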