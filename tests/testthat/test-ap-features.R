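test_that("AP features match constructed arithmetic and closed forms", {
  # idealized square AP: -80 mV baseline, +40 mV held 200 ms, instant return
  fs <- 10000
  v <- rep(-80, 3 * fs)
  for (t0 in c(0.5, 1.5, 2.5))
    v[(t0 * fs):((t0 + 0.2) * fs)] <- 40
  tr <- voltage_trace(v, fs, "ap")
  beats <- detect_ap_beats(tr)
  f <- suppressWarnings(compute_ap_features(tr, beats))
  expect_equal(f$per_beat$peak_mv, rep(40, 3), tolerance = 1e-6)
  expect_equal(f$per_beat$mdp_mv, rep(-80, 3), tolerance = 1e-6)
  expect_equal(f$per_beat$apa_mv, rep(120, 3), tolerance = 1e-6)
  expect_equal(f$per_beat$apd90_ms[2], 200, tolerance = 2)  # one-sample scale

  # generator closed forms on a noise-free train
  g <- gen_ap_train(rate_bpm = 40, duration_s = 30, noise_sd_mv = 0, seed = 1,
                    waveform = list(upstroke_vps = 100, apd90_ms = 300))
  fg <- compute_ap_features(g$trace, detect_ap_beats(g$trace))
  expect_equal(unname(fg$summary$apd90_ms["mean"]), 300, tolerance = 0.1)
  expect_equal(unname(fg$summary$dvdt_max_vps["mean"]), 100, tolerance = 2)
  expect_equal(unname(fg$summary$mdp_mv["mean"]), -70, tolerance = 0.01)
  expect_equal(unname(fg$summary$peak_mv["mean"]), 35, tolerance = 0.01)
  expect_equal(fg$beat_rate_bpm, 40, tolerance = 0.01)
})

test_that("features are invariant to time translation", {
  g <- gen_ap_train(rate_bpm = 40, duration_s = 15, noise_sd_mv = 0, seed = 2)
  b <- detect_ap_beats(g$trace)
  f0 <- compute_ap_features(g$trace, b)
  sh <- voltage_trace(g$trace$samples, g$trace$rate_hz, "ap", t0_s = 7)
  bs <- detect_ap_beats(sh)
  f1 <- compute_ap_features(sh, bs)
  expect_equal(f1$per_beat$t_activation_s, f0$per_beat$t_activation_s + 7,
               tolerance = 1e-9)
  for (col in c("mdp_mv", "peak_mv", "apa_mv", "dvdt_max_vps", "apd90_ms"))
    expect_equal(f1$per_beat[[col]], f0$per_beat[[col]], tolerance = 1e-9)
})

test_that("APD90 scales with the repolarization duration", {
  vals <- c(200, 300, 450)
  meas <- vapply(vals, function(a) {
    g <- gen_ap_train(rate_bpm = 40, duration_s = 12, noise_sd_mv = 0,
                      seed = 1, waveform = list(apd90_ms = a))
    unname(compute_ap_features(g$trace,
                               detect_ap_beats(g$trace))$summary$apd90_ms["mean"])
  }, numeric(1))
  expect_equal(meas, vals, tolerance = 0.001)
})

test_that("beats that never repolarize to the 90% level are flagged missing", {
  fs <- 1000
  v <- rep(-80, 3 * fs)
  v[(0.5 * fs):(1.0 * fs)] <- 40
  v[(1.5 * fs):(3 * fs)] <- 40          # second AP never repolarizes
  tr <- voltage_trace(v, fs, "ap")
  beats <- detect_ap_beats(tr)
  expect_warning(f <- compute_ap_features(tr, beats), "90%")
  expect_true(is.na(f$per_beat$apd90_ms[2]))
})

test_that("paced_epochs partitions the canonical protocol exactly", {
  proto <- list(pulses_per_train = 20, rates_hz = c(0.5, 1, 1.5, 2), pause_s = 20)
  stim <- numeric(); t <- 0
  for (r in proto$rates_hz) {
    stim <- c(stim, t + (0:19) / r)
    t <- t + 20 / r + proto$pause_s
  }
  ep <- paced_epochs(stim, proto)
  expect_equal(nrow(ep), 8)
  expect_equal(ep$type, rep(c("train", "pause"), 4))
  tr1 <- ep[ep$rate_hz == 0.5 & ep$type == "train", ]
  expect_equal(tr1$t_start_s, 0)
  expect_equal(tr1$t_end_s, 40)          # 20 pulses at 0.5 Hz
  pa1 <- ep[ep$rate_hz == 0.5 & ep$type == "pause", ]
  expect_equal(pa1$t_end_s - pa1$t_start_s, 20)

  expect_equal(nrow(paced_epochs(numeric(), proto)), 0)
  expect_error(paced_epochs(stim[-1], proto), "expected 80")
})
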