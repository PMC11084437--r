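#' Default action-potential waveform parameters
#'
#' Phenomenological spontaneous-AP waveform for cultured cardiomyocytes:
#' maximal diastolic potential (mV), peak overshoot (mV), duration at 90%
#' repolarization (ms) and maximal upstroke velocity (V/s). Values sit in
#' the range typical of spontaneously firing iPSC-derived cardiomyocytes.
#'
#' @return Named list with `mdp_mv`, `peak_mv`, `apd90_ms`, `upstroke_vps`.
#' @export
ap_waveform_defaults <- function() {
  list(mdp_mv = -70, peak_mv = 35, apd90_ms = 300, upstroke_vps = 40)
}

# Geometry of the constructed AP, all closed form. The upstroke is a raised
# cosine whose maximal slope equals upstroke_vps at its centre (the
# "activation time"); the peak is a shallow parabolic dome (unique maximum
# under noise); repolarization is exponential with tau tuned so the time
# from activation to the 90%-repolarization crossing equals apd90_ms.
ap_geometry <- function(waveform, dome_ms = 60, dome_drop_mv = 1) {
  apa <- waveform$peak_mv - waveform$mdp_mv
  rise <- apa - dome_drop_mv                      # mV covered by the upstroke
  t_up <- rise * pi / (2 * waveform$upstroke_vps) # ms
  l90 <- waveform$peak_mv - 0.9 * apa
  tau <- (waveform$apd90_ms - t_up / 2 - dome_ms) /
    log(rise / (0.1 * apa))
  if (tau <= 0)
    stop("apd90_ms too short for the upstroke + dome geometry")
  list(apa = apa, rise = rise, t_up_ms = t_up, dome_ms = dome_ms,
       dome_drop_mv = dome_drop_mv, tau_ms = tau, l90 = l90)
}

# Add one half-sine subthreshold bump (centre t_mid, width w, height amp
# above the current trace) into sample vector v; returns v.
add_bump <- function(v, rate_hz, t0_s, t_mid, amp, width_s) {
  i0 <- floor((t_mid - width_s / 2 - t0_s) * rate_hz) + 1L
  i1 <- ceiling((t_mid + width_s / 2 - t0_s) * rate_hz) + 1L
  i0 <- max(i0, 1L); i1 <- min(i1, length(v))
  if (i1 <= i0) return(v)
  tt <- (seq(i0, i1) - 1L) / rate_hz + t0_s
  ph <- (tt - (t_mid - width_s / 2)) / width_s
  sel <- ph >= 0 & ph <= 1
  v[seq(i0, i1)[sel]] <- v[seq(i0, i1)[sel]] + amp * sin(pi * ph[sel])
  v
}

#' Generate a spontaneous action-potential train with ground truth
#'
#' Builds a noise-controlled intracellular trace of regularly scheduled
#' action potentials and optionally injects labelled arrhythmogenic events:
#' delayed afterdepolarizations (`"dad"`, damped subthreshold oscillation
#' runs after an AP), oscillatory pre-potentials (`"opp"`, growing runs
#' ending in an AP) and failed beats (`"failed"`, a subthreshold deflection
#' replacing a scheduled AP).
#'
#' Each event spec is a list with `kind` and `beat` (1-based index into the
#' scheduled beats) plus optional `n_osc`, `amp_mv`, `width_ms`,
#' `spacing_ms`, `delay_ms`. Unspecified event parameters are drawn from
#' the generator conventions: DAD amplitude uniform on 5-15 mV with damping
#' factor 0.65 per cycle and 1-3 oscillations; OPP runs of 3-6 oscillations
#' growing by 25% per cycle. The recording emulated is a patch-clamp AP
#' trace digitized at 10 kHz.
#'
#' @param rate_bpm Spontaneous beat rate, beats per minute.
#' @param duration_s Trace duration in seconds.
#' @param waveform Waveform parameter list, see [ap_waveform_defaults()].
#' @param events List of event specs (see Details), or `NULL`.
#' @param noise_sd_mv SD of the band-limited Gaussian noise (mV).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @param rate_hz Sampling rate (default 10 kHz).
#' @param first_beat_s Onset time of the first scheduled AP.
#' @param beat_schedule Optional explicit vector of AP onset times (s),
#'   overriding the regular schedule (used e.g. for pacing protocols).
#'
#' @return A list with `trace` (a [voltage_trace()]) and `truth`
#'   (beat times = AP peak times, the injected event table, and the
#'   closed-form waveform timing constants).
#' @export
gen_ap_train <- function(rate_bpm = 40, duration_s = 30,
                         waveform = ap_waveform_defaults(),
                         events = NULL, noise_sd_mv = 0.5, seed = 1,
                         rate_hz = 10000, first_beat_s = 0.3,
                         beat_schedule = NULL) {
  stopifnot(rate_bpm > 0, duration_s > 0)
  waveform <- utils::modifyList(ap_waveform_defaults(), waveform)
  if (waveform$apd90_ms >= 60000 / rate_bpm)
    stop("apd90_ms must be shorter than the beat period")
  geo <- ap_geometry(waveform)
  dt <- 1 / rate_hz
  n <- round(duration_s * rate_hz)
  period <- 60 / rate_bpm

  snap <- function(t) round(t * rate_hz) / rate_hz
  if (is.null(beat_schedule)) {
    onsets <- snap(seq(first_beat_s, duration_s - (geo$t_up_ms + geo$dome_ms) / 1000,
                       by = period))
  } else onsets <- snap(sort(beat_schedule))

  with_seed(seed, {
    # resolve event specs against the schedule before drawing the trace
    ev <- list()
    failed_idx <- integer()
    if (!is.null(events)) {
      for (spec in events) {
        kind <- match.arg(spec$kind, c("dad", "opp", "failed"))
        b <- spec$beat
        if (is.null(b) || b < 1L || b > length(onsets))
          stop("event beat index out of range: ", b)
        width <- (spec$width_ms %||% 80) / 1000
        spacing <- (spec$spacing_ms %||% 160) / 1000
        if (kind == "dad") {
          n_osc <- spec$n_osc %||% sample(1:3, 1L)
          amp0 <- spec$amp_mv %||% stats::runif(1L, 5, 15)
          amps <- amp0 * 0.65^(seq_len(n_osc) - 1L)
          delay <- (spec$delay_ms %||% 150) / 1000
          t_first <- onsets[b] + (geo$t_up_ms / 2 + waveform$apd90_ms) / 1000 + delay
          mids <- t_first + (seq_len(n_osc) - 1L) * spacing
          if (b < length(onsets) &&
              max(mids) + width / 2 > onsets[b + 1L] - 0.05)
            stop("DAD at beat ", b, " collides with the next AP's refractory window")
        } else if (kind == "opp") {
          n_osc <- spec$n_osc %||% sample(3:6, 1L)
          amp_f <- spec$amp_mv %||% stats::runif(1L, 8, 15)
          amps <- amp_f / 1.25^(rev(seq_len(n_osc)) - 1L)
          gap <- 0.03
          mids <- onsets[b] - gap - (rev(seq_len(n_osc)) - 0.5) * spacing
          if (b > 1L) {
            prev_end <- onsets[b - 1L] +
              (geo$t_up_ms / 2 + waveform$apd90_ms) / 1000 + 0.05
            if (min(mids) - width / 2 < prev_end)
              stop("OPP at beat ", b, " collides with the preceding AP")
          } else if (min(mids) - width / 2 < 0)
            stop("OPP at beat ", b, " starts before the trace")
        } else { # failed beat
          amps <- spec$amp_mv %||% 10
          mids <- onsets[b] + (geo$t_up_ms + geo$dome_ms / 2) / 1000
          failed_idx <- c(failed_idx, b)
        }
        ev[[length(ev) + 1L]] <-
          list(kind = switch(kind, dad = "DAD", opp = "OPP", failed = "failed_beat"),
               beat = b, t_peaks = mids, amps = amps,
               t_start = min(mids) - width / 2, t_end = max(mids) + width / 2,
               width_s = width)
      }
    }

    fired <- if (length(failed_idx)) onsets[-failed_idx] else onsets

    # waveform synthesis (segment-wise, closed form)
    v <- rep(waveform$mdp_mv, n)
    tt <- (seq_len(n) - 1L) * dt
    t_up <- geo$t_up_ms / 1000; t_dome <- geo$dome_ms / 1000
    tau <- geo$tau_ms / 1000
    for (k in seq_along(fired)) {
      on_k <- fired[k]
      i0 <- round(on_k * rate_hz) + 1L
      if (i0 > n) next
      i_up1 <- min(round((on_k + t_up) * rate_hz) + 1L, n)
      i_dm1 <- min(round((on_k + t_up + t_dome) * rate_hz) + 1L, n)
      i_end <- if (k < length(fired)) min(round(fired[k + 1L] * rate_hz), n) else n
      if (i_up1 > i0) {
        ph <- (tt[i0:i_up1] - on_k) / t_up
        v[i0:i_up1] <- waveform$mdp_mv + geo$rise * (1 - cos(pi * pmin(ph, 1))) / 2
      }
      if (i_dm1 > i_up1) {
        ph <- (tt[i_up1:i_dm1] - (on_k + t_up)) / t_dome
        v[i_up1:i_dm1] <- waveform$peak_mv -
          geo$dome_drop_mv * (2 * pmin(ph, 1) - 1)^2
      }
      if (i_end > i_dm1) {
        te <- tt[i_dm1:i_end] - (on_k + t_up + t_dome)
        # normalized exponential: reaches MDP exactly at the next onset while
        # keeping the 90%-repolarization crossing at apd90 from activation
        t_rep <- te[length(te)] + dt
        tc <- (waveform$apd90_ms - geo$t_up_ms / 2 - geo$dome_ms) / 1000
        frac90 <- 0.1 * geo$apa / geo$rise
        tau_k <- if (t_rep > tc * 1.05) {
          gfun <- function(ta) {
            E <- exp(-t_rep / ta)
            (exp(-tc / ta) - E) / (1 - E) - frac90
          }
          tryCatch(stats::uniroot(gfun, c(tc / 20, t_rep * 5),
                                  tol = 1e-12)$root,
                   error = function(e) tau)
        } else tau
        E <- exp(-t_rep / tau_k)
        v[i_dm1:i_end] <- waveform$mdp_mv +
          geo$rise * pmax((exp(-te / tau_k) - E) / (1 - E), 0)
      }
    }
    for (e in ev)
      for (j in seq_along(e$t_peaks))
        v <- add_bump(v, rate_hz, 0, e$t_peaks[j], e$amps[j], e$width_s)

    if (noise_sd_mv > 0) {
      w <- c(-3, 12, 17, 12, -3) / 35
      scale <- noise_sd_mv / sqrt(sum(w^2))
      v <- v + sg_smooth(stats::rnorm(n, 0, scale), 5L)
    }

    peak_times <- fired + t_up + t_dome / 2
    truth <- list(
      beat_times_s = peak_times[peak_times <= duration_s],
      onsets_s = fired,
      activation_times_s = fired + t_up / 2,
      injected_events = ev,
      waveform = waveform,
      geometry = geo)
    list(trace = voltage_trace(v, rate_hz, "ap",
                               meta = list(generator = "gen_ap_train", seed = seed)),
         truth = truth)
  })
}
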