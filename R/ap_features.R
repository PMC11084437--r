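#' Per-beat action-potential characteristics
#'
#' For every detected beat: MDP (minimum of the diastolic interval
#' preceding the upstroke), peak, APA = peak - MDP, maximal upstroke
#' velocity dV/dt max (from the Savitzky-Golay-smoothed derivative within a
#' 50 ms window ending at the peak), activation time (time of dV/dt max,
#' refined to sub-sample precision) and APD90 (time from activation until
#' the falling phase first crosses `peak - 0.9 * APA`, linearly
#' interpolated). APD90 is referenced to activation, not to the peak; this
#' convention is recorded in the result and configurable.
#'
#' Beats whose repolarization never reaches the 90% level before the next
#' beat get `NA` APD90 with a warning.
#'
#' @param trace A [voltage_trace()], modality `"ap"`.
#' @param beats A [beat_series()] with >= 2 beats.
#' @param apd_reference `"activation"` (default) or `"peak"`.
#' @param dvdt_window_s Window before the peak searched for dV/dt max.
#' @param smooth_window Savitzky-Golay window (samples, odd).
#'
#' @return An object of class `ap_features`: element `per_beat` (data.frame
#'   with `t_beat_s`, `mdp_mv`, `peak_mv`, `apa_mv`, `dvdt_max_vps`,
#'   `apd90_ms`, `t_activation_s`), `summary` (mean and sample SD per
#'   feature), `beat_rate_bpm`, and the conventions used.
#' @export
compute_ap_features <- function(trace, beats, apd_reference = c("activation", "peak"),
                                dvdt_window_s = 0.05, smooth_window = 5L) {
  stopifnot(inherits(trace, "voltage_trace"), inherits(beats, "beat_series"))
  if (trace$modality != "ap") stop("compute_ap_features expects an 'ap' trace")
  apd_reference <- match.arg(apd_reference)
  bt <- beats$beat_times_s
  if (length(bt) < 2L) stop("need at least 2 beats")
  fs <- trace$rate_hz
  # running median for amplitude readout: the identity on monotone segments
  # (so closed-form waveform values survive exactly) and free of the
  # overshoot a polynomial smoother shows at step-like transitions
  v <- stats::runmed(trace$samples, smooth_window, endrule = "keep")
  n <- length(v)
  t_of <- function(i) trace$t0_s + (i - 1) / fs        # fractional ok
  i_of <- function(t) round((t - trace$t0_s) * fs) + 1L
  dvdt <- smoothed_derivative(trace$samples, fs, smooth_window) / 1000 # V/s

  m <- length(bt)
  out <- data.frame(t_beat_s = bt, mdp_mv = NA_real_, peak_mv = NA_real_,
                    apa_mv = NA_real_, dvdt_max_vps = NA_real_,
                    apd90_ms = NA_real_, t_activation_s = NA_real_)
  half_pk <- max(1L, round(0.015 * fs))
  cross_prev <- 1L    # index bounding the previous beat's repolarization
  n_missing <- 0L
  for (k in seq_len(m)) {
    ip <- min(max(i_of(bt[k]), 1L), n)
    lo <- max(1L, ip - half_pk); hi <- min(n, ip + half_pk)
    ipk <- lo - 1L + which.max(v[lo:hi])
    peak <- v[ipk]
    # dV/dt max in the window ending at the peak
    w0 <- max(1L, ipk - round(dvdt_window_s * fs))
    irel <- which.max(dvdt[w0:ipk])
    iact <- refine_extremum(dvdt[w0:ipk], irel) + (w0 - 1L)
    dmax <- max(dvdt[w0:ipk])
    t_act <- t_of(iact)
    # MDP in the diastolic interval [previous 90% crossing, upstroke)
    d_hi <- max(cross_prev + 1L, floor(iact) - round(0.010 * fs))
    d_lo <- max(1L, cross_prev)
    mdp <- min(v[d_lo:d_hi])
    apa <- peak - mdp
    # APD90: falling crossing of (peak - 0.9 APA) after the peak
    lev <- peak - 0.9 * apa
    nxt <- if (k < m) min(n, i_of(bt[k + 1L]) - round(0.010 * fs)) else n
    seg <- v[ipk:nxt]
    below <- which(seg <= lev)
    if (length(below)) {
      icr <- ipk - 1L + falling_cross(seg, below[1L], lev) + 1
      ref_t <- if (apd_reference == "activation") t_act else t_of(ipk)
      out$apd90_ms[k] <- (t_of(icr) - ref_t) * 1000
      cross_prev <- ipk - 1L + below[1L]
    } else {
      n_missing <- n_missing + 1L
      cross_prev <- ipk
    }
    out$mdp_mv[k] <- mdp; out$peak_mv[k] <- peak; out$apa_mv[k] <- apa
    out$dvdt_max_vps[k] <- dmax; out$t_activation_s[k] <- t_act
  }
  if (n_missing)
    warning(n_missing, " beat(s) never reached the 90% repolarization level; APD90 set NA")
  summ <- lapply(c("mdp_mv", "peak_mv", "apa_mv", "dvdt_max_vps", "apd90_ms"),
                 function(f) {
                   x <- out[[f]][is.finite(out[[f]])]
                   c(mean = mean(x), sd = stats::sd(x), n = length(x))
                 })
  names(summ) <- c("mdp_mv", "peak_mv", "apa_mv", "dvdt_max_vps", "apd90_ms")
  structure(list(per_beat = out, summary = summ,
                 beat_rate_bpm = 60 * length(beats$ibis_s) / sum(beats$ibis_s),
                 apd_reference = apd_reference),
            class = "ap_features")
}

#' @export
print.ap_features <- function(x, ...) {
  cat(sprintf("<ap_features> %d beats, rate %.1f BPM (APD90 referenced to %s)\n",
              nrow(x$per_beat), x$beat_rate_bpm, x$apd_reference))
  for (f in names(x$summary))
    cat(sprintf("  %-13s %8.2f +/- %.2f (n=%d)\n", f,
                x$summary[[f]]["mean"], x$summary[[f]]["sd"],
                as.integer(x$summary[[f]]["n"])))
  invisible(x)
}

#' Label pacing-protocol epochs
#'
#' Splits a stimulus-time list into per-train windows and post-train pause
#' windows for a fixed protocol of `pulses_per_train` pulses delivered at
#' each rate in `rates_hz` (in order), separated by `pause_s` pauses. All
#' windows are half-open `[t_start, t_end)`.
#'
#' @param stim_times Stimulus times in seconds (may be empty).
#' @param protocol List with `pulses_per_train` (default 20), `rates_hz`
#'   (default `c(0.5, 1, 1.5, 2)`), `pause_s` (default 20).
#' @param rate_tol Fractional tolerance for verifying intra-train intervals
#'   against the nominal rate.
#' @return Data.frame with columns `rate_hz`, `type` (`"train"`/`"pause"`),
#'   `t_start_s`, `t_end_s`; zero rows for an empty stimulus list.
#' @export
paced_epochs <- function(stim_times,
                         protocol = list(pulses_per_train = 20,
                                         rates_hz = c(0.5, 1.0, 1.5, 2.0),
                                         pause_s = 20),
                         rate_tol = 0.01) {
  empty <- data.frame(rate_hz = numeric(), type = character(),
                      t_start_s = numeric(), t_end_s = numeric())
  if (!length(stim_times)) return(empty)
  stim_times <- sort(as.numeric(stim_times))
  ppt <- protocol$pulses_per_train
  rates <- protocol$rates_hz
  if (length(stim_times) != ppt * length(rates))
    stop("expected ", ppt * length(rates), " stimuli (",
         ppt, " per train x ", length(rates), " trains), got ",
         length(stim_times))
  out <- empty
  for (r in seq_along(rates)) {
    tr <- stim_times[((r - 1L) * ppt + 1L):(r * ppt)]
    ibi <- diff(tr)
    if (any(abs(ibi - 1 / rates[r]) > rate_tol / rates[r]))
      stop("train ", r, " intervals inconsistent with ", rates[r], " Hz")
    t_end <- tr[ppt] + 1 / rates[r]
    out <- rbind(out,
                 data.frame(rate_hz = rates[r], type = "train",
                            t_start_s = tr[1L], t_end_s = t_end),
                 data.frame(rate_hz = rates[r], type = "pause",
                            t_start_s = t_end, t_end_s = t_end + protocol$pause_s))
  }
  out
}
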