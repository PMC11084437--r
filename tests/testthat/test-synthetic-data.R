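test_that("generators are deterministic given a seed", {
  a <- gen_ap_train(duration_s = 5, seed = 42)
  b <- gen_ap_train(duration_s = 5, seed = 42)
  expect_identical(a$trace$samples, b$trace$samples)
  expect_identical(a$truth$beat_times_s, b$truth$beat_times_s)

  i1 <- gen_ibi_series("bimodal", c(0.8, 1.6), 0.03, 50, seed = 7)
  i2 <- gen_ibi_series("bimodal", c(0.8, 1.6), 0.03, 50, seed = 7)
  expect_identical(i1$beat_times_s, i2$beat_times_s)

  m1 <- gen_cell_image(nc_ratio = 1.3, seed = 3)
  m2 <- gen_cell_image(nc_ratio = 1.3, seed = 3)
  expect_identical(m1$pair$signal, m2$pair$signal)
})

test_that("AP train schedules and labels beats and events exactly", {
  g <- gen_ap_train(rate_bpm = 60, duration_s = 60, noise_sd_mv = 0, seed = 1)
  expect_length(g$truth$beat_times_s, 60)
  expect_length(g$truth$injected_events, 0)

  gf <- gen_ap_train(rate_bpm = 60, duration_s = 60, noise_sd_mv = 0, seed = 1,
                     events = list(list(kind = "failed", beat = 5)))
  expect_length(gf$truth$beat_times_s, 59)
  expect_equal(gf$truth$injected_events[[1]]$kind, "failed_beat")

  # every injected event appears exactly once in the ground truth
  ev <- list(list(kind = "dad", beat = 3), list(kind = "opp", beat = 8),
             list(kind = "failed", beat = 12))
  gm <- gen_ap_train(rate_bpm = 30, duration_s = 40, events = ev, seed = 2)
  expect_equal(vapply(gm$truth$injected_events, `[[`, "", "kind"),
               c("DAD", "OPP", "failed_beat"))

  # event colliding with the next AP's refractory window errors
  expect_error(
    gen_ap_train(rate_bpm = 120, duration_s = 10, seed = 1,
                 events = list(list(kind = "dad", beat = 2, delay_ms = 400,
                                    n_osc = 3))),
    "collides")
  expect_error(gen_ap_train(rate_bpm = 100, duration_s = 10,
                            waveform = list(apd90_ms = 700)), "period")
})

test_that("IBI series match their generating process", {
  u <- gen_ibi_series("unimodal", 0.6, 0.02, 500, seed = 3)
  expect_lt(abs(mean(u$ibis_s) - 0.6), 0.01)  # 3 SE band at n = 500

  b <- gen_ibi_series("bimodal", c(0.8, 1.6), 0.03, 400, seed = 7)
  bm <- detect_bimodality(b)
  expect_true(bm$bimodal)
  expect_lt(abs(bm$mode_estimates_s[1] / 0.8 - 1), 0.05)
  expect_lt(abs(bm$mode_estimates_s[2] / 1.6 - 1), 0.05)

  # degenerate limit: tiny dispersion collapses onto the mode
  d <- gen_ibi_series("unimodal", 0.5, 1e-9, 3, seed = 1)
  expect_equal(d$ibis_s, rep(0.5, 3), tolerance = 1e-6)

  expect_error(gen_ibi_series("unimodal", 0.5, 0, 10), "sd_s")
  expect_error(gen_ibi_series("bimodal", c(1, 1), 0.1, 10), "distinct")
})

test_that("ECG generator books VA episodes and caffeine scales transients", {
  ep <- data.frame(t_start_s = 1000, duration_s = 360)
  gh <- gen_ecg_beats(va_episodes = ep, seed = 1)
  expect_equal(gh$truth$total_va_s, 360)
  expect_error(gen_ecg_beats(duration_s = 100,
                             va_episodes = data.frame(t_start_s = 90,
                                                      duration_s = 30)),
               "outside")

  gc <- gen_ca_trace(duration_s = 60, amplitude = 0.8, caffeine_time_s = 30,
                     f_caf = 2, noise_frac = 0, seed = 1)
  caf <- gc$truth$transients[gc$truth$transients$caffeine, ]
  expect_equal(caf$amplitude, 1.6)
})

test_that("cell image generator encodes the prescribed densities", {
  g <- gen_cell_image(nc_ratio = 1.0, noise_frac = 0, seed = 1)
  masks <- segment_cell(g$pair, 50, 10)
  expect_equal(measure_nc_ratio(g$pair, masks)$nc_ratio, 1.0)

  pre <- gen_cell_image(preset = "control", seed = 2)
  expect_equal(pre$truth$nc_ratio, 1.30)
  expect_error(gen_cell_image(preset = "nope"), "unknown preset")
  expect_error(gen_cell_image(nc_ratio = 2, nucleus_radius = 40), "inside")
})
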