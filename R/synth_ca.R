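#' Generate a synthetic Ca2+ ratio trace with optional caffeine bolus
#'
#' Each beat produces one transient: a normalized exponential rise that
#' reaches exactly `baseline + amplitude` after `3 * tau_rise_s`, followed
#' by a normalized exponential decay returning exactly to baseline at the
#' next beat. The normalization keeps the per-transient amplitude exact by
#' construction while preserving closed-form maximal rates, which are
#' stored in the ground truth:
#' rise max = `A / (tau_rise * (1 - exp(-T_rise/tau_rise)))` at onset,
#' decay max = `A / (tau_decay * (1 - exp(-T_decay/tau_decay)))` at the peak.
#' Beat onsets are snapped to the sample grid so beat-aligned ensemble
#' averaging is exact.
#'
#' A caffeine bolus at `caffeine_time_s` produces one transient of
#' amplitude `f_caf * amplitude` with a slower decay, followed by a
#' quiescent interval such that the first resumed transient peaks exactly
#' `gap_s` seconds after the caffeine peak, after which the regular
#' transients resume — the abrupt amplitude surge, decline and resumption
#' seen in caffeine-response protocols.
#'
#' @param duration_s Trace duration (s).
#' @param beat_period_s Interval between transient onsets (s).
#' @param amplitude Transient amplitude in ratio units.
#' @param baseline Diastolic ratio level.
#' @param tau_rise_s,tau_decay_s Rise / decay time constants (s).
#' @param noise_frac Noise SD as a fraction of `baseline`.
#' @param caffeine_time_s Time of the caffeine bolus, or `NULL`.
#' @param f_caf Caffeine amplitude factor.
#' @param gap_s Peak-to-peak quiescence after the caffeine transient (s).
#' @param tau_decay_caf_s Decay constant of the caffeine transient.
#' @param rate_hz Sampling rate (default 100 Hz, the conventional
#'   fluorescence acquisition rate).
#' @param seed Integer seed.
#'
#' @return List with `trace` ([voltage_trace()], modality `"ca"`) and
#'   `truth` (per-transient table of onset, peak time, amplitude and the
#'   analytic maximal rates; caffeine descriptor when present).
#' @export
gen_ca_trace <- function(duration_s = 60, beat_period_s = 1.5,
                         amplitude = 0.8, baseline = 1.0,
                         tau_rise_s = 0.15, tau_decay_s = 0.40,
                         noise_frac = 0.02, caffeine_time_s = NULL,
                         f_caf = 2.0, gap_s = 8, tau_decay_caf_s = 1.2,
                         rate_hz = 100, seed = 1) {
  stopifnot(duration_s > 0, beat_period_s > 0, amplitude > 0)
  dt <- 1 / rate_hz
  snap <- function(t) round(t * rate_hz) / rate_hz
  t_rise <- snap(3 * tau_rise_s)
  if (t_rise >= beat_period_s)
    stop("beat_period_s must exceed the rise duration 3*tau_rise_s")
  if (!is.null(caffeine_time_s) &&
      (caffeine_time_s <= 0 || caffeine_time_s >= duration_s))
    stop("caffeine_time_s must lie inside the trace")

  # build the onset schedule
  onsets <- snap(seq(1.0, duration_s - beat_period_s, by = beat_period_s))
  caf <- NULL
  if (!is.null(caffeine_time_s)) {
    k <- which(onsets >= caffeine_time_s)[1L]
    if (is.na(k) || k <= 3L)
      stop("need at least 3 pre-caffeine transients before caffeine_time_s")
    caf_onset <- onsets[k]
    resume_onset <- snap(caf_onset + t_rise + gap_s - t_rise) # peak-to-peak gap
    post <- snap(seq(resume_onset, duration_s - beat_period_s, by = beat_period_s))
    onsets <- c(onsets[seq_len(k - 1L)], caf_onset, post)
    caf <- list(onset_s = caf_onset, peak_s = caf_onset + t_rise,
                amplitude = f_caf * amplitude, gap_s = gap_s)
  }

  n <- round(duration_s * rate_hz)
  tt <- (seq_len(n) - 1L) * dt
  v <- rep(baseline, n)
  m <- length(onsets)
  tr_tab <- data.frame(onset_s = onsets, peak_s = NA_real_,
                       amplitude = NA_real_, rise_rate = NA_real_,
                       decay_rate = NA_real_, caffeine = FALSE)
  for (k in seq_len(m)) {
    on_k <- onsets[k]
    t_end <- if (k < m) onsets[k + 1L] else min(on_k + beat_period_s, duration_s)
    is_caf <- !is.null(caf) && on_k == caf$onset_s
    A <- if (is_caf) caf$amplitude else amplitude
    td <- if (is_caf) tau_decay_caf_s else tau_decay_s
    t_dec <- t_end - (on_k + t_rise)
    if (t_dec <= dt) next
    i0 <- round(on_k * rate_hz) + 1L
    ip <- min(round((on_k + t_rise) * rate_hz) + 1L, n)
    ie <- min(round(t_end * rate_hz), n)
    if (ip > i0) {
      te <- tt[i0:ip] - on_k
      v[i0:ip] <- baseline + A * (1 - exp(-te / tau_rise_s)) /
        (1 - exp(-t_rise / tau_rise_s))
    }
    if (ie > ip) {
      te <- tt[ip:ie] - (on_k + t_rise)
      E <- exp(-t_dec / td)
      v[ip:ie] <- baseline + A * (exp(-te / td) - E) / (1 - E)
    }
    tr_tab$peak_s[k] <- on_k + t_rise
    tr_tab$amplitude[k] <- A
    tr_tab$rise_rate[k] <- A / (tau_rise_s * (1 - exp(-t_rise / tau_rise_s)))
    tr_tab$decay_rate[k] <- A / (td * (1 - exp(-t_dec / td)))
    tr_tab$caffeine[k] <- is_caf
  }
  tr_tab <- tr_tab[!is.na(tr_tab$peak_s), ]

  with_seed(seed, {
    if (noise_frac > 0) {
      w <- c(-3, 12, 17, 12, -3) / 35
      v <- v + sg_smooth(stats::rnorm(n, 0, noise_frac * baseline / sqrt(sum(w^2))), 5L)
    }
    list(trace = voltage_trace(v, rate_hz, "ca",
                               meta = list(generator = "gen_ca_trace", seed = seed)),
         truth = list(transients = tr_tab, caffeine = caf,
                      params = list(amplitude = amplitude, baseline = baseline,
                                    tau_rise_s = tau_rise_s,
                                    tau_decay_s = tau_decay_s,
                                    t_rise_s = t_rise)))
  })
}
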