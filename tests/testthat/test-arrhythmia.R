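test_that("injected events are detected and classified by kind", {
  g <- gen_ap_train(rate_bpm = 30, duration_s = 40, seed = 5,
                    events = list(list(kind = "dad", beat = 3, n_osc = 2,
                                       amp_mv = 10),
                                  list(kind = "opp", beat = 8, n_osc = 4),
                                  list(kind = "failed", beat = 12)))
  b <- detect_ap_beats(g$trace)
  cand <- detect_subthreshold_events(g$trace, b)
  ev <- classify_events(cand, b)
  expect_equal(ev$kind, c("DAD", "OPP", "failed_beat"))
  expect_equal(ev$n_oscillations, c(2L, 4L, 1L))
  # the DAD candidate sits at the injected oscillation time
  inj <- g$truth$injected_events[[1]]
  expect_lt(abs(cand$t_s[1] - inj$t_peaks[1]), 0.005)

  # noise-free regular train: no candidates at all
  g0 <- gen_ap_train(rate_bpm = 30, duration_s = 30, noise_sd_mv = 0, seed = 1)
  b0 <- detect_ap_beats(g0$trace)
  expect_equal(nrow(detect_subthreshold_events(g0$trace, b0)), 0)

  one <- beat_series(1)
  expect_error(detect_subthreshold_events(g0$trace, one), ">= 2 beats")
})

test_that("arrhythmia summaries implement the counting rules exactly", {
  ev0 <- classify_events(data.frame(t_s = numeric(), amp_mv = numeric(),
                                    diastole = integer()),
                         regular_beats(1, 10))
  s0 <- summarize_arrhythmia(ev0, 60)
  expect_equal(s0$occurrence_per_min, 0)
  expect_false(s0$is_arrhythmogenic)

  ev6 <- data.frame(kind = rep("DAD", 6), t_start_s = 1:6, t_end_s = 1:6 + 0.1,
                    n_oscillations = 1L, max_amp_mv = 5)
  s6 <- summarize_arrhythmia(ev6, 180)
  expect_equal(s6$occurrence_per_min, 2.0)
  expect_true(s6$is_arrhythmogenic)

  s2 <- summarize_arrhythmia(ev6[1:2, ], 10)
  expect_false(s2$is_arrhythmogenic)     # below the >= 3 events rule
  s3 <- summarize_arrhythmia(ev6[1:3, ], 1e6)
  expect_true(s3$is_arrhythmogenic)      # duration-independent

  expect_error(summarize_arrhythmia(ev6, -1), "> 0")

  # occurrence scales inversely with duration for fixed events
  expect_equal(summarize_arrhythmia(ev6, 60)$occurrence_per_min,
               2 * summarize_arrhythmia(ev6, 120)$occurrence_per_min)
})

test_that("percent arrhythmogenic reproduces printed cohort arithmetic", {
  mk <- function(n, k, g) data.frame(group = g,
                                     is_arrhythmogenic = rep(c(TRUE, FALSE),
                                                             c(k, n - k)))
  tab <- cohort_table(rbind(mk(8, 3, "a"), mk(37, 26, "b"), mk(5, 0, "c")))
  out <- percent_arrhythmogenic(tab)
  expect_equal(out$pct[out$group == "a"], 37.5)
  expect_equal(round(out$pct[out$group == "b"], 1), 70.3)
  expect_equal(out$pct[out$group == "c"], 0)

  empty <- cohort_table(mk(4, 1, "a"), groups = c("a", "b"))
  expect_warning(res <- percent_arrhythmogenic(empty), "empty group")
  expect_true(is.na(res$pct[res$group == "b"]))
})

test_that("VA episode detection applies the sustained >30 s rule", {
  # constructed beat series: 5 Hz sinus, one fast insert
  mk_beats <- function(ep_start, ep_dur, dur = 5400, fast_rr = 0.08) {
    t <- seq(0.2, dur, by = 0.2)
    ins <- seq(ep_start, ep_start + ep_dur, by = fast_rr)
    t <- sort(c(t[t < ep_start | t > ep_start + ep_dur], ins))
    beat_series(t, "ecg", duration_s = dur)
  }
  r20 <- detect_va_episodes(mk_beats(1000, 20))
  expect_equal(nrow(r20$episodes), 1)
  expect_false(r20$any_sustained_va)     # 20 s is not sustained

  r6m <- detect_va_episodes(mk_beats(1000, 360))
  expect_true(r6m$any_sustained_va)
  expect_equal(r6m$fractional_duration_pct, 100 * 360 / 5400, tolerance = 0.01)

  sinus <- beat_series(seq(0.2, 5400, by = 0.2), "ecg", duration_s = 5400)
  rs <- detect_va_episodes(sinus)
  expect_equal(nrow(rs$episodes), 0)
  expect_equal(rs$fractional_duration_pct, 0)

  expect_error(detect_va_episodes(beat_series(seq(0, 30, 0.2), "ecg")), "60 s")
  expect_error(detect_va_episodes(sinus, baseline_window_s = 6000), "baseline")
})

test_that("pacing response flags events and firing cessation per rate", {
  r <- run_figure_preset("fig10_pacing", seed = 3)
  expect_true(all(r$checks))
  expect_error(score_pacing_response(NULL, regular_beats(1, 5),
                                     data.frame(rate_hz = 1, type = "pause",
                                                t_start_s = c(0, 1),
                                                t_end_s = c(2, 3))),
               "overlapping")
})

test_that("event-kind classification accuracy holds across seeds", {
  total <- 0L; correct <- 0L
  for (s in 1:6) {
    ev <- list(list(kind = "dad", beat = 3, n_osc = 2),
               list(kind = "opp", beat = 7),
               list(kind = "failed", beat = 11),
               list(kind = "dad", beat = 14, n_osc = 1))
    g <- gen_ap_train(rate_bpm = 30, duration_s = 40, seed = 100 + s,
                      events = ev)
    b <- detect_ap_beats(g$trace)
    det <- suppressWarnings(
      classify_events(detect_subthreshold_events(g$trace, b), b))
    for (te in g$truth$injected_events) {
      total <- total + 1L
      hit <- which(abs(det$t_start_s - te$t_start) < 0.15)
      if (length(hit) && det$kind[hit[1]] == te$kind) correct <- correct + 1L
    }
  }
  expect_gte(correct / total, 0.9)
})
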