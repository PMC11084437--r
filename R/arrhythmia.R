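#' Detect candidate subthreshold diastolic deflections
#'
#' Scans the diastolic intervals of an AP recording (everything outside
#' each beat's upstroke-to-90%-repolarization window plus a margin) for
#' local maxima whose prominence lies between `min_amp_mv` and
#' `max_amp_frac_apa` times the median APA. These candidates are the raw
#' material for [classify_events()].
#'
#' The amplitude thresholds are declared conventions: the source
#' recordings define the event morphologies only qualitatively, so the
#' defaults (2 mV floor, 0.5 APA ceiling) are configurable.
#'
#' @param trace A [voltage_trace()], modality `"ap"`.
#' @param beats A [beat_series()] with >= 2 beats.
#' @param min_amp_mv Minimum prominence (mV).
#' @param max_amp_frac_apa Maximum prominence as a fraction of median APA.
#' @param smooth_ms Smoothing window for the diastolic search (ms); heavy
#'   relative to the feature smoother because the events are >= 50 ms wide.
#' @param min_sep_ms Minimum separation between candidates (ms).
#' @param margin_s Margin added around each AP's excluded window (s).
#' @return Data.frame with `t_s`, `amp_mv` and `diastole` (index of the
#'   beat preceding the candidate; 0 = before the first beat).
#' @export
detect_subthreshold_events <- function(trace, beats, min_amp_mv = 2,
                                       max_amp_frac_apa = 0.5,
                                       smooth_ms = 5, min_sep_ms = 40,
                                       margin_s = 0.03) {
  stopifnot(inherits(trace, "voltage_trace"), inherits(beats, "beat_series"))
  if (length(beats$beat_times_s) < 2L)
    stop("need >= 2 beats to define diastole")
  feats <- suppressWarnings(compute_ap_features(trace, beats))
  pb <- feats$per_beat
  med_apa <- stats::median(pb$apa_mv, na.rm = TRUE)
  fs <- trace$rate_hz
  win <- round(smooth_ms / 1000 * fs)
  if (win %% 2L == 0L) win <- win + 1L
  v <- sg_smooth(trace$samples, max(3L, win))
  n <- length(v)
  tt <- trace$t0_s + (seq_len(n) - 1L) / fs

  # excluded windows: upstroke start (activation - 30 ms) .. 90% crossing
  ex_start <- pb$t_activation_s - 0.03 - margin_s
  apd_s <- ifelse(is.finite(pb$apd90_ms), pb$apd90_ms / 1000,
                  0.5 * stats::median(beats$ibis_s))
  ex_end <- pb$t_activation_s + apd_s + margin_s
  excluded <- rep(FALSE, n)
  # trace edges keep raw (unsmoothed) samples over half a smoothing window;
  # exclude them so endpoint noise cannot seed candidates
  excluded[seq_len(win)] <- TRUE
  excluded[(n - win + 1L):n] <- TRUE
  for (k in seq_len(nrow(pb))) {
    i0 <- max(1L, floor((ex_start[k] - trace$t0_s) * fs) + 1L)
    i1 <- min(n, ceiling((ex_end[k] - trace$t0_s) * fs) + 1L)
    excluded[i0:i1] <- TRUE
  }

  out <- data.frame(t_s = numeric(), amp_mv = numeric(), diastole = integer())
  r <- rle(!excluded)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  sep <- max(1L, round(min_sep_ms / 1000 * fs))
  for (s in which(r$values)) {
    i0 <- starts[s]; i1 <- ends[s]
    if (i1 - i0 < sep) next
    seg <- v[i0:i1]
    pk <- local_maxima(seg, min_sep = sep)
    if (!length(pk)) next
    proms <- peak_prominences(seg, pk)
    for (j in seq_along(pk)) {
      amp <- proms[j]
      if (amp >= min_amp_mv && amp <= max_amp_frac_apa * med_apa) {
        t_pk <- tt[i0 - 1L + pk[j]]
        out <- rbind(out, data.frame(
          t_s = t_pk, amp_mv = amp,
          diastole = findInterval(t_pk, beats$beat_times_s)))
      }
    }
  }
  out[order(out$t_s), , drop = FALSE]
}

#' Classify candidate deflections into arrhythmogenic event kinds
#'
#' Rules applied in order to each diastolic run of candidates:
#' \enumerate{
#'   \item OPP — a run of >= 3 candidates with strictly increasing
#'     amplitudes that terminates in an action potential;
#'   \item failed beat — a candidate (or damped run) lying within
#'     `timing_frac` of the robust expected beat time (previous beat +
#'     running median IBI) whose enclosing IBI exceeds `ibi_factor` times
#'     that median — the deflection stands where an AP was due,
#'     interrupting the regular firing pattern;
#'   \item DAD — any remaining run with non-increasing amplitudes after
#'     the first oscillation, following a normally timed AP.
#' }
#' Unclassifiable runs are kept with kind `"unknown"` and a warning; no
#' candidate is dropped silently. The running median IBI uses the
#' preceding `median_window` IBIs, tolerating slow rate drift.
#'
#' @param candidates Data.frame from [detect_subthreshold_events()].
#' @param beats The [beat_series()] the candidates were detected against.
#' @param timing_frac Half-width of the failed-beat timing window, as a
#'   fraction of the running median IBI.
#' @param ibi_factor Enclosing-IBI threshold (in median-IBI units) for a
#'   failed beat.
#' @param median_window Number of preceding IBIs in the running median.
#' @param amp_slack_mv Noise slack allowed when testing amplitude ordering.
#' @return Data.frame of events: `kind` (`"DAD"`, `"OPP"`,
#'   `"failed_beat"`, `"unknown"`), `t_start_s`, `t_end_s`,
#'   `n_oscillations`, `max_amp_mv`, plus the per-oscillation amplitudes in
#'   attribute `"amplitudes"`.
#' @export
classify_events <- function(candidates, beats, timing_frac = 0.25,
                            ibi_factor = 1.5, median_window = 10,
                            amp_slack_mv = 0.5) {
  stopifnot(inherits(beats, "beat_series"))
  empty <- data.frame(kind = character(), t_start_s = numeric(),
                      t_end_s = numeric(), n_oscillations = integer(),
                      max_amp_mv = numeric())
  attr(empty, "amplitudes") <- list()
  if (!nrow(candidates)) return(empty)
  if (is.unsorted(candidates$t_s)) stop("candidates must be time-sorted")
  bt <- beats$beat_times_s
  ibis <- beats$ibis_s
  m <- length(bt)
  run_med <- function(j) {
    # median IBI over the <= median_window IBIs preceding diastole j
    if (j >= 2L) idx <- max(1L, j - median_window):(j - 1L) else idx <- integer()
    if (!length(idx)) stats::median(ibis) else stats::median(ibis[idx])
  }
  rows <- list(); amps_out <- list(); n_unknown <- 0L
  for (j in sort(unique(candidates$diastole))) {
    cc <- candidates[candidates$diastole == j, , drop = FALSE]
    amps <- cc$amp_mv
    k <- length(amps)
    med <- run_med(j)
    increasing <- k >= 2L && all(diff(amps) > 0)
    non_increasing <- k == 1L || all(diff(amps) <= amp_slack_mv)
    encl_ibi <- if (j >= 1L && j < m) bt[j + 1L] - bt[j] else NA_real_
    expected <- if (j >= 1L) bt[j] + med else NA_real_
    near_expected <- j >= 1L &&
      any(abs(cc$t_s - expected) <= timing_frac * med)
    kind <- if (k >= 3L && increasing && j < m) {
      "OPP"
    } else if (near_expected && !is.na(encl_ibi) && encl_ibi > ibi_factor * med) {
      "failed_beat"
    } else if (near_expected && j == m &&
               beats$duration_s - bt[m] > ibi_factor * med) {
      "failed_beat"
    } else if (non_increasing && j >= 1L) {
      "DAD"
    } else "unknown"
    if (kind == "unknown") n_unknown <- n_unknown + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      kind = kind, t_start_s = min(cc$t_s) - 0.04, t_end_s = max(cc$t_s) + 0.04,
      n_oscillations = k, max_amp_mv = max(amps))
    amps_out[[length(amps_out) + 1L]] <- amps
  }
  out <- do.call(rbind, rows)
  attr(out, "amplitudes") <- amps_out
  if (n_unknown)
    warning(n_unknown, " candidate run(s) could not be classified; kept as 'unknown'")
  out
}

#' Summarize arrhythmogenic events for one recording
#'
#' A cell is called arrhythmogenic when it shows at least three
#' arrhythmogenic events; the occurrence is the mean number of events per
#' minute of recording.
#'
#' @param events Event data.frame from [classify_events()].
#' @param duration_s Recording duration in seconds (> 0).
#' @return An `arrhythmia_summary`: `n_events`, `occurrence_per_min`,
#'   `is_arrhythmogenic`, `per_kind` counts, and the event table.
#' @export
summarize_arrhythmia <- function(events, duration_s) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be > 0")
  n <- if (is.null(events)) 0L else nrow(events)
  kinds <- c("DAD", "OPP", "failed_beat", "unknown")
  per_kind <- if (n) table(factor(events$kind, levels = kinds))
              else table(factor(character(), levels = kinds))
  structure(list(events = events, n_events = n,
                 occurrence_per_min = n / (duration_s / 60),
                 is_arrhythmogenic = n >= 3L,
                 per_kind = per_kind, duration_s = duration_s),
            class = "arrhythmia_summary")
}

#' @export
print.arrhythmia_summary <- function(x, ...) {
  cat(sprintf("<arrhythmia_summary> %d events in %.1f min (%.2f events/min)%s\n",
              x$n_events, x$duration_s / 60, x$occurrence_per_min,
              if (x$is_arrhythmogenic) " - ARRHYTHMOGENIC (>= 3 events)" else ""))
  print(x$per_kind)
  invisible(x)
}

#' Percentage of arrhythmogenic cells per group
#'
#' @param cohort A [cohort_table()] with a logical `is_arrhythmogenic`
#'   column.
#' @return Data.frame with `group`, `n`, `n_arrhythmogenic`, `pct`.
#' @export
percent_arrhythmogenic <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!"is_arrhythmogenic" %in% names(cohort))
    stop("cohort must have an 'is_arrhythmogenic' column")
  groups <- attr(cohort, "groups")
  out <- data.frame(group = groups, n = NA_integer_,
                    n_arrhythmogenic = NA_integer_, pct = NA_real_)
  for (i in seq_along(groups)) {
    sel <- cohort$group == groups[i]
    out$n[i] <- sum(sel)
    if (!any(sel)) {
      warning("empty group '", groups[i], "': percentage set NA")
      next
    }
    out$n_arrhythmogenic[i] <- sum(cohort$is_arrhythmogenic[sel])
    out$pct[i] <- 100 * out$n_arrhythmogenic[i] / out$n[i]
  }
  out
}

#' Flag pacing-induced arrhythmias per pacing rate
#'
#' A cell is flagged arrhythmic at rate r when at least one classified
#' event, or a firing cessation (no beat for more than `cessation_factor`
#' times the median pre-pacing IBI), occurs within the post-train pause
#' window of r.
#'
#' @param trace A [voltage_trace()], modality `"ap"`.
#' @param beats Detected [beat_series()] for the trace.
#' @param epochs Epoch table from [paced_epochs()].
#' @param cessation_factor Cessation threshold in pre-pacing median-IBI
#'   units.
#' @return Data.frame with `rate_hz`, `n_events`, `cessation`,
#'   `arrhythmic`.
#' @export
score_pacing_response <- function(trace, beats, epochs, cessation_factor = 2) {
  pauses <- epochs[epochs$type == "pause", , drop = FALSE]
  if (!nrow(pauses)) return(data.frame(rate_hz = numeric(), n_events = integer(),
                                       cessation = logical(), arrhythmic = logical()))
  ord <- order(epochs$t_start_s)
  eo <- epochs[ord, ]
  if (any(eo$t_start_s[-1L] < eo$t_end_s[-nrow(eo)]))
    stop("overlapping epochs")
  bt <- beats$beat_times_s
  pre <- bt[bt < min(epochs$t_start_s)]
  med_pre <- if (length(pre) >= 3L) stats::median(diff(pre))
             else stats::median(beats$ibis_s)
  ev <- classify_events(detect_subthreshold_events(trace, beats), beats)
  thr <- cessation_factor * med_pre
  out <- data.frame(rate_hz = pauses$rate_hz, n_events = 0L,
                    cessation = FALSE, arrhythmic = FALSE)
  for (i in seq_len(nrow(pauses))) {
    a <- pauses$t_start_s[i]; b <- pauses$t_end_s[i]
    out$n_events[i] <- sum(ev$t_start_s >= a & ev$t_start_s < b)
    inb <- bt[bt >= a & bt < b]
    marks <- c(a, inb, b)
    out$cessation[i] <- any(diff(marks) > thr)
    out$arrhythmic[i] <- out$n_events[i] > 0L || out$cessation[i]
  }
  out
}

#' Detect ventricular-arrhythmia episodes in a whole-heart beat series
#'
#' The baseline RR is the median RR over the initial `baseline_window_s`.
#' Beats whose RR falls below `baseline / rate_factor` are VA beats;
#' consecutive VA intervals merge into episodes, episodes closer than
#' `min_gap_s` are merged, and an episode is sustained when it lasts more
#' than `sustained_s` (default 30 s). The fractional duration is the
#' percentage of the recording spent in episodes.
#'
#' @param beats A [beat_series()] (typically modality `"ecg"`) spanning at
#'   least `baseline_window_s`.
#' @param baseline_window_s Initial window used for the baseline RR (s).
#' @param rate_factor RR acceleration factor defining a VA beat.
#' @param min_gap_s Episodes closer than this merge.
#' @param sustained_s Sustained-episode duration threshold (s); an episode
#'   is sustained only when strictly longer.
#' @return A `va_report`: `episodes` (data.frame `t_start_s`, `t_end_s`,
#'   `duration_s`, `sustained`), `any_sustained_va`,
#'   `fractional_duration_pct`, `baseline_rr_s`.
#' @export
detect_va_episodes <- function(beats, baseline_window_s = 60,
                               rate_factor = 1.5, min_gap_s = 2,
                               sustained_s = 30) {
  stopifnot(inherits(beats, "beat_series"))
  bt <- beats$beat_times_s
  if (length(bt) < 2L || beats$duration_s < 60)
    stop("need at least 60 s of beats")
  if (baseline_window_s > beats$duration_s)
    stop("baseline window longer than the recording")
  rr <- beats$ibis_s
  base_sel <- bt[-length(bt)] < bt[1L] + baseline_window_s
  baseline <- stats::median(rr[base_sel])
  fast <- rr < baseline / rate_factor
  ep <- data.frame(t_start_s = numeric(), t_end_s = numeric())
  if (any(fast)) {
    r <- rle(fast)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (s in which(r$values))
      ep <- rbind(ep, data.frame(t_start_s = bt[starts[s]],
                                 t_end_s = bt[ends[s] + 1L]))
    # merge episodes separated by less than min_gap_s
    merged <- ep[1L, , drop = FALSE]
    if (nrow(ep) > 1L) for (i in 2:nrow(ep)) {
      if (ep$t_start_s[i] - merged$t_end_s[nrow(merged)] < min_gap_s)
        merged$t_end_s[nrow(merged)] <- ep$t_end_s[i]
      else merged <- rbind(merged, ep[i, ])
    }
    ep <- merged
  }
  ep$duration_s <- ep$t_end_s - ep$t_start_s
  ep$sustained <- ep$duration_s > sustained_s
  structure(list(episodes = ep,
                 any_sustained_va = any(ep$sustained),
                 fractional_duration_pct =
                   100 * sum(ep$duration_s) / beats$duration_s,
                 baseline_rr_s = baseline),
            class = "va_report")
}

#' @export
print.va_report <- function(x, ...) {
  cat(sprintf("<va_report> %d episode(s), %.2f%% of the recording%s\n",
              nrow(x$episodes), x$fractional_duration_pct,
              if (x$any_sustained_va) ", sustained VA present (>30 s)" else ""))
  invisible(x)
}
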