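#' Extract Ca2+ transient features
#'
#' Transients are segmented at prominence-detected peaks of the smoothed
#' trace; each transient's baseline is the pre-upstroke local minimum, the
#' amplitude `r_amp` is peak minus baseline, and the maximal rates of rise
#' and decay (+d[Ca]/dt, -d[Ca]/dt) are the extrema of the first
#' differences of the raw trace over the transient. Rates are reported as
#' positive magnitudes in ratio units per second.
#'
#' When at least `n_average + 1` transients are present, a beat-aligned
#' ensemble average of `n_average` (default 20) consecutive transients is
#' formed (aligned at the mid-rise crossing, where the slope is steepest)
#' and the features are recomputed on the average — the averaged features
#' are the headline per-recording values, mirroring standard
#' fluorescence-workstation practice. The averaged maximal rates are the
#' analytic derivatives of the exponential transient model fitted to the
#' average; the per-transient rates use raw first differences, because
#' polynomial smoothing systematically underestimates the rate at the
#' transient onset at fluorescence acquisition rates (see the methods
#' vignette for both choices).
#'
#' @param trace A [voltage_trace()], modality `"ca"`.
#' @param min_prom_frac Peak prominence threshold as a fraction of the
#'   robust trace range.
#' @param min_sep_s Minimum peak separation (s).
#' @param n_average Number of consecutive transients in the ensemble
#'   average.
#' @return An object of class `ca_features`: `per_transient` (data.frame
#'   `t_peak_s`, `t_baseline_s`, `baseline`, `r_amp`, `dca_rise_max`,
#'   `dca_decay_max`), `ensemble` (same features recomputed on the
#'   average, or `NULL` with a warning when fewer than `n_average + 1`
#'   transients exist), `n_transients`.
#' @export
extract_ca_transients <- function(trace, min_prom_frac = 0.25,
                                  min_sep_s = 0.25, n_average = 20) {
  stopifnot(inherits(trace, "voltage_trace"))
  if (trace$modality != "ca") stop("extract_ca_transients expects a 'ca' trace")
  v <- trace$samples
  fs <- trace$rate_hz
  sm <- sg_smooth(v, 5L)
  n <- length(v)
  rng <- diff(stats::quantile(sm, c(0.02, 0.98), names = FALSE))
  empty <- structure(list(per_transient = data.frame(), ensemble = NULL,
                          n_transients = 0L), class = "ca_features")
  if (rng <= 0) return(empty)
  sep <- max(2L, round(min_sep_s * fs))
  pk <- local_maxima(sm, min_sep = sep)
  if (!length(pk)) return(empty)
  pk <- pk[peak_prominences(sm, pk) >= min_prom_frac * rng]
  if (!length(pk)) return(empty)
  # refine each peak on the raw trace: smoothing plus noise can displace the
  # detected maximum on the slow exponential top, so search a window of
  # ~80 ms around it
  ref <- max(2L, round(0.08 * fs))
  pk <- vapply(pk, function(i) {
    lo <- max(1L, i - ref); hi <- min(n, i + ref)
    as.integer(lo - 1L + which.max(v[lo:hi]))
  }, integer(1))
  pk <- sort(unique(pk))
  if (length(pk) > 1L) pk <- pk[c(TRUE, diff(pk) >= sep)]

  m <- length(pk)
  tb <- integer(m)
  for (k in seq_len(m)) {
    lo <- if (k == 1L) 1L else pk[k - 1L]
    tb[k] <- lo - 1L + which.min(v[lo:pk[k]])
  }
  per <- data.frame(t_peak_s = trace$t0_s + (pk - 1L) / fs,
                    t_baseline_s = trace$t0_s + (tb - 1L) / fs,
                    baseline = v[tb], r_amp = v[pk] - v[tb],
                    dca_rise_max = NA_real_, dca_decay_max = NA_real_)
  for (k in seq_len(m)) {
    e <- if (k < m) tb[k + 1L] else n
    d <- diff(v[tb[k]:e]) * fs
    per$dca_rise_max[k] <- max(d)
    per$dca_decay_max[k] <- -min(d)
  }

  ens <- NULL
  if (m >= n_average + 1L) {
    # Beat-aligned average of the first n_average consecutive transients
    # whose full windows fit inside the trace. Alignment uses the mid-rise
    # crossing, where the slope is steepest, so the alignment jitter under
    # noise stays below one sample and the average keeps a sharp peak.
    mid <- vapply(seq_len(m), function(k) {
      seg <- v[tb[k]:pk[k]]
      lev <- v[tb[k]] + 0.5 * (v[pk[k]] - v[tb[k]])
      as.integer(tb[k] - 1L + which(seg >= lev)[1L])
    }, integer(1))
    pre <- round(stats::median(mid - tb)) + max(2L, round(0.02 * fs))
    post <- round(stats::median(c(tb[-1L], n) - mid))
    ok <- which(mid - pre >= 1L & mid + post <= n)
    sel <- NULL
    for (s in seq_len(max(0L, m - n_average + 1L))) {
      cand <- s:(s + n_average - 1L)
      if (all(cand %in% ok)) { sel <- cand; break }
    }
    if (!is.null(sel)) {
      mat <- vapply(mid[sel], function(i) v[(i - pre):(i + post)],
                    numeric(pre + post + 1L))
      avg <- rowMeans(mat)
      ipk <- which.max(avg)
      ib <- which.min(avg[seq_len(ipk)])
      fit <- fit_transient_model(avg, fs, ipk - 1L)
      ens <- list(r_amp = avg[ipk] - avg[ib],
                  dca_rise_max = fit$rise_max,
                  dca_decay_max = fit$decay_max,
                  baseline = avg[ib], n = n_average, average = avg,
                  peak_offset = ipk - 1L, rate_hz = fs, fit = fit)
    }
  } else {
    warning("fewer than ", n_average + 1L,
            " transients: per-transient features only, no ensemble average")
  }
  structure(list(per_transient = per, ensemble = ens, n_transients = m),
            class = "ca_features")
}

#' @export
print.ca_features <- function(x, ...) {
  cat(sprintf("<ca_features> %d transients\n", x$n_transients))
  if (x$n_transients) {
    p <- x$per_transient
    cat(sprintf("  per-transient: r_amp %.3f, +dCa/dt %.2f, -dCa/dt %.2f (medians)\n",
                stats::median(p$r_amp), stats::median(p$dca_rise_max),
                stats::median(p$dca_decay_max)))
  }
  if (!is.null(x$ensemble))
    cat(sprintf("  %d-transient average: r_amp %.3f, +dCa/dt %.2f, -dCa/dt %.2f\n",
                x$ensemble$n, x$ensemble$r_amp, x$ensemble$dca_rise_max,
                x$ensemble$dca_decay_max))
  invisible(x)
}

# Least-squares fit of the normalized-exponential transient model (rise
# reaching the full amplitude after three rise constants, decay returning to
# baseline at the end of the window) to a beat-aligned average, with a free
# time offset (the averaged top is rounded, so the argmax is a poor time
# origin). Returns the parameters plus the analytic maximal rates of the
# fitted waveform.
fit_transient_model <- function(avg, fs, peak_offset) {
  t <- (seq_along(avg) - (peak_offset + 1L)) / fs   # 0 at the aligned peak
  Td <- (length(avg) - peak_offset - 1L) / fs
  model <- function(par) {
    b <- par[1L]; A <- par[2L]
    tr <- exp(par[3L]); td <- exp(par[4L])
    ts <- t - par[5L]
    y <- numeric(length(t))
    ris <- ts <= 0
    up <- ts[ris] + 3 * tr
    y[ris] <- b + A * ifelse(up > 0, (1 - exp(-up / tr)) / (1 - exp(-3)), 0)
    E <- exp(-Td / td)
    y[!ris] <- b + A * (exp(-ts[!ris] / td) - E) / (1 - E)
    y
  }
  sse <- function(par) sum((avg - model(par))^2)
  init <- c(min(avg), max(avg) - min(avg),
            log(max(peak_offset / fs, 0.05) / 3), log(max(Td, 0.05) / 3), 0)
  fit <- stats::optim(init, sse, method = "Nelder-Mead",
                      control = list(maxit = 10000, reltol = 1e-12))
  b <- fit$par[1L]; A <- fit$par[2L]
  tr <- exp(fit$par[3L]); td <- exp(fit$par[4L])
  E <- exp(-Td / td)
  list(baseline = b, amplitude = A, tau_rise_s = tr, tau_decay_s = td,
       t_offset_s = fit$par[5L], convergence = fit$convergence,
       rise_max = A / (tr * (1 - exp(-3))),
       decay_max = A / (td * (1 - E)))
}

#' Recover transient kinetics from the ensemble average
#'
#' Fits the normalized-exponential transient model (rise reaching the full
#' amplitude after three rise constants, decay returning to baseline at
#' the end of the cycle) to the beat-aligned ensemble average by least
#' squares, estimating the amplitude and the rise/decay time constants.
#' Fitting the whole waveform pools all samples of the average, so the
#' estimates are far less noise-sensitive than inverting the maximal
#' rates.
#'
#' @param features A `ca_features` object with an ensemble average.
#' @return List with `amplitude`, `tau_rise_s`, `tau_decay_s`, `baseline`,
#'   and the optimizer convergence code.
#' @export
estimate_ca_kinetics <- function(features) {
  stopifnot(inherits(features, "ca_features"))
  e <- features$ensemble
  if (is.null(e)) stop("ensemble average required (>= 21 transients)")
  f <- e$fit %||% fit_transient_model(e$average, e$rate_hz, e$peak_offset)
  list(amplitude = f$amplitude, tau_rise_s = f$tau_rise_s,
       tau_decay_s = f$tau_decay_s, baseline = f$baseline,
       convergence = f$convergence)
}

#' Quantify the response to a caffeine bolus
#'
#' Caffeine opens the sarcoplasmic-reticulum ryanodine receptors, dumping
#' the SR Ca2+ store into the cytosol: the trace shows one abrupt large
#' transient, a decline, and resumption of regular transients. Three
#' parameters quantify the response: (i) recovery time — from the peak of
#' the caffeine-induced rise to the first measurable subsequent transient
#' peak; (ii) the percent change of the caffeine transient amplitude
#' relative to the mean pre-caffeine amplitude; (iii) the fold change of
#' the caffeine transient area relative to the mean pre-caffeine transient
#' area (areas above each transient's own baseline, integrated from onset
#' to 95% return toward baseline).
#'
#' "Measurable" means an amplitude of at least `measurable_frac` of the
#' mean pre-caffeine amplitude (a declared convention).
#'
#' @param trace A [voltage_trace()], modality `"ca"`.
#' @param caffeine_time_s Bolus time (must lie inside the trace).
#' @param measurable_frac Resumption amplitude threshold.
#' @return A `caffeine_response`: `recovery_time_s` (NA with a warning if
#'   transients never resume), `amp_change_pct`, `area_fold_change`.
#' @export
analyze_caffeine <- function(trace, caffeine_time_s, measurable_frac = 0.25) {
  stopifnot(inherits(trace, "voltage_trace"))
  tmax <- trace$t0_s + trace_duration(trace)
  if (caffeine_time_s <= trace$t0_s || caffeine_time_s >= tmax)
    stop("caffeine_time_s must lie inside the trace")
  feats <- suppressWarnings(extract_ca_transients(trace))
  per <- feats$per_transient
  pre <- per[per$t_peak_s < caffeine_time_s, , drop = FALSE]
  if (nrow(pre) < 3L) stop("need >= 3 pre-caffeine transients")
  post <- per[per$t_peak_s >= caffeine_time_s, , drop = FALSE]
  if (!nrow(post)) stop("no transient after caffeine_time_s")
  caf <- post[which.max(post$r_amp), ]
  pre_amp <- mean(pre$r_amp)

  v <- trace$samples; fs <- trace$rate_hz
  idx_of <- function(t) round((t - trace$t0_s) * fs) + 1L
  area_of <- function(row, t_next_baseline) {
    i0 <- idx_of(row$t_baseline_s)
    ip <- idx_of(row$t_peak_s)
    lev <- row$baseline + 0.05 * row$r_amp
    iend <- idx_of(t_next_baseline)
    seg <- v[ip:iend]
    ret <- which(seg <= lev)
    i1 <- if (length(ret)) ip - 1L + ret[1L] else iend
    y <- v[i0:i1] - row$baseline
    (sum(y) - (y[1L] + y[length(y)]) / 2) / fs    # trapezoid
  }
  nb <- c(per$t_baseline_s[-1L], tmax)   # next-transient baseline per row
  pre_area <- mean(vapply(seq_len(nrow(pre)), function(i)
    area_of(per[i, ], nb[i]), numeric(1)))
  caf_i <- match(caf$t_peak_s, per$t_peak_s)
  caf_area <- area_of(caf, nb[caf_i])

  resumed <- post[post$t_peak_s > caf$t_peak_s &
                    post$r_amp >= measurable_frac * pre_amp, , drop = FALSE]
  recovery <- if (nrow(resumed)) resumed$t_peak_s[1L] - caf$t_peak_s else {
    warning("no measurable transient after the caffeine peak; recovery time NA")
    NA_real_
  }
  structure(list(recovery_time_s = recovery,
                 amp_change_pct = 100 * (caf$r_amp - pre_amp) / pre_amp,
                 area_fold_change = caf_area / pre_area,
                 caffeine_peak_s = caf$t_peak_s,
                 pre_amp_mean = pre_amp),
            class = "caffeine_response")
}

#' @export
print.caffeine_response <- function(x, ...) {
  cat(sprintf("<caffeine_response> recovery %.2f s, amplitude change %+.1f%%, area fold %.2f\n",
              x$recovery_time_s, x$amp_change_pct, x$area_fold_change))
  invisible(x)
}
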