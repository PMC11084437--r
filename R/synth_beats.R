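#' Generate a synthetic inter-beat-interval series
#'
#' Unimodal series are i.i.d. truncated-normal IBIs. Bimodal series are a
#' two-state process whose state switches with probability `switch_prob`
#' between beats, so that consecutive IBIs jump between two clouds with
#' minimal overlap: with `switch_prob = 1` the process alternates strictly
#' (two off-diagonal Poincare clouds); with the default 0.5 the lag-1 pairs
#' populate all four state combinations (the four-cloud Poincare pattern of
#' bimodally firing preparations).
#'
#' @param mode `"unimodal"` or `"bimodal"`.
#' @param modes_s One (unimodal) or two distinct (bimodal) mode values, s.
#' @param sd_s Within-mode SD of the IBIs, s (> 0).
#' @param n Number of IBIs (>= 3).
#' @param seed Integer seed.
#' @param switch_prob Probability of switching modes between consecutive
#'   IBIs (bimodal only).
#' @param t0_s Time of the first beat.
#' @param source_modality Modality tag for the returned [beat_series()].
#'
#' @return A [beat_series()] with `n + 1` beats; the generating descriptor
#'   is attached as attribute `"ibi_process"`.
#' @export
gen_ibi_series <- function(mode = c("unimodal", "bimodal"), modes_s, sd_s, n,
                           seed = 1, switch_prob = 0.5, t0_s = 0,
                           source_modality = "ap") {
  mode <- match.arg(mode)
  if (sd_s <= 0) stop("sd_s must be > 0")
  if (n < 3) stop("n must be >= 3")
  if (mode == "bimodal") {
    if (length(modes_s) != 2L || modes_s[1] == modes_s[2])
      stop("bimodal mode needs two distinct mode values")
  } else if (length(modes_s) != 1L) stop("unimodal mode needs one mode value")
  lo <- 0.05 * min(modes_s)   # truncation keeps IBIs physically positive
  with_seed(seed, {
    rt_norm <- function(m, s, k) {
      x <- stats::rnorm(k, m, s)
      while (any(x <= lo)) x[x <= lo] <- stats::rnorm(sum(x <= lo), m, s)
      x
    }
    if (mode == "unimodal") {
      ibis <- rt_norm(modes_s, sd_s, n)
      states <- rep(1L, n)
    } else {
      states <- integer(n)
      states[1L] <- sample(1:2, 1L)
      if (n > 1L) {
        flip <- stats::runif(n - 1L) < switch_prob
        for (i in 2:n) states[i] <- if (flip[i - 1L]) 3L - states[i - 1L] else states[i - 1L]
      }
      ibis <- rt_norm(modes_s[states], sd_s, n)
    }
    bs <- beat_series(t0_s + cumsum(c(0, ibis)), source_modality)
    attr(bs, "ibi_process") <- list(mode = mode, modes_s = modes_s, sd_s = sd_s,
                                    switch_prob = switch_prob, states = states)
    bs
  })
}

# Biphasic extracellular spike template: sharp negative lobe then a smaller
# positive lobe. The ground-truth spike time is the centre of the negative
# lobe (its absolute extremum).
mea_template <- function(rate_hz, amp_uv, w1_s = 0.003, w2_s = 0.004) {
  t1 <- seq(0, w1_s, by = 1 / rate_hz)
  t2 <- seq(1 / rate_hz, w2_s, by = 1 / rate_hz)
  c(-amp_uv * sin(pi * t1 / w1_s), 0.6 * amp_uv * sin(pi * t2 / w2_s))
}

#' Generate a synthetic microelectrode-array electrogram
#'
#' A biphasic spike template is placed at each beat time on top of slow
#' baseline wander and band-limited Gaussian noise, emulating an
#' extracellular field-potential recording from a beating cardiomyocyte
#' cluster.
#'
#' @param beats Optional [beat_series()] giving the spike times; if `NULL`
#'   a regular train is generated.
#' @param n_spikes Number of spikes when `beats` is `NULL`.
#' @param spike_rate_hz Mean spike rate when `beats` is `NULL`.
#' @param ibi_jitter_frac Fractional SD of the IBIs for the regular train.
#' @param amp_uv Spike amplitude (uV).
#' @param noise_sd_uv Noise SD (uV).
#' @param wander_uv,wander_hz Amplitude and frequency of baseline wander.
#' @param rate_hz Sampling rate (default 1 kHz).
#' @param seed Integer seed.
#'
#' @return List with `trace` ([voltage_trace()], modality `"mea"`) and
#'   `truth` (spike times in seconds).
#' @export
gen_mea_trace <- function(beats = NULL, n_spikes = 120, spike_rate_hz = 1,
                          ibi_jitter_frac = 0.03, amp_uv = 100,
                          noise_sd_uv = 5, wander_uv = 30, wander_hz = 0.3,
                          rate_hz = 1000, seed = 1) {
  with_seed(seed, {
    if (is.null(beats)) {
      ibis <- stats::rnorm(n_spikes - 1L, 1 / spike_rate_hz,
                           ibi_jitter_frac / spike_rate_hz)
      ibis <- pmax(ibis, 0.2 / spike_rate_hz)
      times <- 1 + cumsum(c(0, ibis))
    } else times <- beats$beat_times_s
    times <- round(times * rate_hz) / rate_hz
    dur <- max(times) + 1
    n <- round(dur * rate_hz)
    v <- wander_uv * sin(2 * pi * wander_hz * (seq_len(n) - 1L) / rate_hz)
    tpl <- mea_template(rate_hz, amp_uv)
    w1_half <- round(0.0015 * rate_hz)          # centre of the negative lobe
    for (tb in times) {
      i0 <- round(tb * rate_hz) + 1L - w1_half
      idx <- seq(i0, length.out = length(tpl))
      ok <- idx >= 1L & idx <= n
      v[idx[ok]] <- v[idx[ok]] + tpl[ok]
    }
    if (noise_sd_uv > 0) {
      w <- c(-3, 12, 17, 12, -3) / 35
      v <- v + sg_smooth(stats::rnorm(n, 0, noise_sd_uv / sqrt(sum(w^2))), 5L)
    }
    list(trace = voltage_trace(v, rate_hz, "mea",
                               meta = list(generator = "gen_mea_trace", seed = seed)),
         truth = list(spike_times_s = times))
  })
}

#' Generate whole-heart beat times with optional ventricular arrhythmia
#' episodes, and optionally a synthetic ECG trace
#'
#' Emulates a rodent-heart rhythm: sinus beats at `sinus_rate_hz` with
#' fractional RR jitter, interrupted by injected ventricular-arrhythmia
#' (VA) episodes during which the rate jumps to `va_rate_hz` with larger
#' irregularity. Episode boundaries are recorded as ground truth.
#'
#' @param duration_s Recording duration (s). Default 5400 s (a 1.5 h
#'   perfusion experiment).
#' @param sinus_rate_hz Sinus beat rate (default 5 Hz, rat range).
#' @param rr_jitter_frac Fractional SD of sinus RR intervals.
#' @param va_episodes `NULL`, or a data.frame / list with `t_start_s` and
#'   `duration_s` per episode.
#' @param va_rate_hz Beat rate inside VA episodes.
#' @param va_jitter_frac Fractional RR SD inside VA episodes.
#' @param seed Integer seed.
#' @param make_trace If `TRUE`, also synthesize an ECG trace with an
#'   R-wave template at each beat.
#' @param trace_rate_hz Sampling rate of the synthesized ECG.
#' @param qrs_amp_uv R-wave amplitude (uV).
#' @param noise_sd_uv ECG noise SD (uV).
#'
#' @return List with `beats` ([beat_series()], modality `"ecg"`), `truth`
#'   (episode table) and, when requested, `trace`.
#' @export
gen_ecg_beats <- function(duration_s = 5400, sinus_rate_hz = 5,
                          rr_jitter_frac = 0.02, va_episodes = NULL,
                          va_rate_hz = 12, va_jitter_frac = 0.08, seed = 1,
                          make_trace = FALSE, trace_rate_hz = 500,
                          qrs_amp_uv = 500, noise_sd_uv = 10) {
  ep <- NULL
  if (!is.null(va_episodes)) {
    ep <- as.data.frame(va_episodes)
    stopifnot(all(c("t_start_s", "duration_s") %in% names(ep)))
    ep$t_end_s <- ep$t_start_s + ep$duration_s
    if (any(ep$t_start_s < 0 | ep$t_end_s > duration_s))
      stop("VA episode outside the recording")
    ep <- ep[order(ep$t_start_s), ]
  }
  in_ep <- function(t) !is.null(ep) && any(t >= ep$t_start_s & t < ep$t_end_s)
  with_seed(seed, {
    times <- numeric(ceiling(duration_s * va_rate_hz) + 16L)
    t <- 0.2; k <- 0L
    while (t < duration_s) {
      k <- k + 1L
      times[k] <- t
      if (in_ep(t)) {
        rr <- 1 / va_rate_hz * (1 + stats::rnorm(1L, 0, va_jitter_frac))
        rr <- max(rr, 0.4 / va_rate_hz)
      } else {
        rr <- 1 / sinus_rate_hz * (1 + stats::rnorm(1L, 0, rr_jitter_frac))
        rr <- max(rr, 0.4 / sinus_rate_hz)
      }
      t <- t + rr
    }
    times <- times[seq_len(k)]
    beats <- beat_series(times, "ecg", duration_s = duration_s)
    out <- list(beats = beats,
                truth = list(va_episodes = ep,
                             total_va_s = if (is.null(ep)) 0 else sum(ep$duration_s)))
    if (make_trace) {
      times_g <- round(times * trace_rate_hz) / trace_rate_hz
      n <- round(duration_s * trace_rate_hz)
      v <- numeric(n)
      tpl <- mea_template(trace_rate_hz, qrs_amp_uv, w1_s = 0.012, w2_s = 0.016)
      half <- round(0.006 * trace_rate_hz)
      for (tb in times_g) {
        i0 <- round(tb * trace_rate_hz) + 1L - half
        idx <- seq(i0, length.out = length(tpl))
        ok <- idx >= 1L & idx <= n
        v[idx[ok]] <- v[idx[ok]] + tpl[ok]
      }
      v <- v + 50 * sin(2 * pi * 0.5 * (seq_len(n) - 1L) / trace_rate_hz)
      if (noise_sd_uv > 0) {
        w <- c(-3, 12, 17, 12, -3) / 35
        v <- v + sg_smooth(stats::rnorm(n, 0, noise_sd_uv / sqrt(sum(w^2))), 5L)
      }
      out$trace <- voltage_trace(v, trace_rate_hz, "ecg",
                                 meta = list(generator = "gen_ecg_beats", seed = seed))
    }
    out
  })
}
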