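test_that("AP beat detection recovers generator truth and edge cases", {
  flat <- voltage_trace(rep(-70, 1000), 10000, "ap")
  expect_length(detect_ap_beats(flat)$beat_times_s, 0)

  g <- gen_ap_train(rate_bpm = 60, duration_s = 60, noise_sd_mv = 0, seed = 1)
  b <- detect_ap_beats(g$trace)
  expect_length(b$beat_times_s, 60)
  expect_lt(max(abs(b$beat_times_s - g$truth$beat_times_s)), 0.002)

  # a failed beat's subthreshold deflection is not counted
  gf <- gen_ap_train(rate_bpm = 60, duration_s = 60, noise_sd_mv = 0, seed = 1,
                     events = list(list(kind = "failed", beat = 5)))
  expect_length(detect_ap_beats(gf$trace)$beat_times_s, 59)

  # offset invariance
  shifted <- voltage_trace(g$trace$samples, g$trace$rate_hz, "ap", t0_s = 10)
  expect_equal(detect_ap_beats(shifted)$beat_times_s, b$beat_times_s + 10)
  expect_error(detect_ap_beats(voltage_trace(1:10, 100, "mea")), "'ap'")
})

test_that("MEA spike detection is MAD-thresholded and polarity invariant", {
  gm <- gen_mea_trace(n_spikes = 120, seed = 5)
  d <- detect_mea_spikes(gm$trace)
  m <- match_times(d$beat_times_s, gm$truth$spike_times_s, 0.02)
  expect_gte(m$tp, 118)
  expect_equal(m$fp, 0)

  inv <- voltage_trace(-gm$trace$samples, gm$trace$rate_hz, "mea")
  expect_equal(detect_mea_spikes(inv)$beat_times_s, d$beat_times_s)

  # pure noise yields no spikes at the default threshold (fixed seed)
  set.seed(11)
  noise <- voltage_trace(rnorm(5000, 0, 5), 1000, "mea")
  expect_length(detect_mea_spikes(noise)$beat_times_s, 0)

  short <- voltage_trace(rnorm(500), 1000, "mea")
  expect_error(detect_mea_spikes(short), "shorter than 1 s")
})

test_that("R-peak detection recovers sinus beats within 10 ms", {
  ge <- gen_ecg_beats(duration_s = 120, make_trace = TRUE, seed = 4)
  d <- detect_r_peaks(ge$trace)
  m <- match_times(d$beat_times_s, ge$beats$beat_times_s, 0.010)
  expect_equal(m$fn, 0)
  expect_equal(m$fp, 0)

  flat <- voltage_trace(rep(0, 5000), 500, "ecg")
  expect_length(detect_r_peaks(flat)$beat_times_s, 0)

  # injecting a VA episode can only add beats
  gv <- gen_ecg_beats(duration_s = 120, make_trace = TRUE, seed = 4,
                      va_episodes = data.frame(t_start_s = 50, duration_s = 30))
  expect_gte(length(detect_r_peaks(gv$trace)$beat_times_s),
             length(d$beat_times_s))

  slow <- voltage_trace(rnorm(500), 50, "ecg")
  expect_error(detect_r_peaks(slow), "bandwidth")
})

test_that("detected beat times are strictly increasing and inside the trace", {
  for (s in 1:3) {
    g <- gen_ap_train(rate_bpm = 50, duration_s = 20, seed = s)
    b <- detect_ap_beats(g$trace)
    expect_true(all(diff(b$beat_times_s) > 0))
    expect_true(all(b$beat_times_s >= g$trace$t0_s &
                      b$beat_times_s <= g$trace$t0_s + trace_duration(g$trace)))
  }
})
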