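test_that("transient features match the generator closed forms", {
  g <- gen_ca_trace(duration_s = 40, noise_frac = 0, seed = 1)
  f <- extract_ca_transients(g$trace)
  tr <- g$truth$transients
  expect_equal(f$n_transients, nrow(tr))
  expect_equal(f$ensemble$r_amp, 0.8, tolerance = 1e-9)
  expect_lt(abs(f$ensemble$dca_rise_max / median(tr$rise_rate) - 1), 0.05)
  expect_lt(abs(f$ensemble$dca_decay_max / median(tr$decay_rate) - 1), 0.05)

  flat <- voltage_trace(rep(1, 500), 100, "ca")
  ff <- suppressWarnings(extract_ca_transients(flat))
  expect_equal(ff$n_transients, 0L)
})

test_that("baseline/peak arithmetic and invariances hold", {
  g <- gen_ca_trace(duration_s = 40, amplitude = 0.8, baseline = 1.0,
                    noise_frac = 0, seed = 1)
  f <- extract_ca_transients(g$trace)
  expect_equal(median(f$per_transient$baseline), 1.0, tolerance = 1e-9)
  expect_equal(median(f$per_transient$r_amp), 0.8, tolerance = 1e-9)

  # per-transient first-difference rates stay within 5% of the closed forms
  tr <- g$truth$transients
  expect_lt(abs(median(f$per_transient$dca_rise_max) /
                  median(tr$rise_rate) - 1), 0.05)
  expect_lt(abs(median(f$per_transient$dca_decay_max) /
                  median(tr$decay_rate) - 1), 0.05)

  # constant offset leaves amplitudes/rates unchanged; scaling is linear
  # (rates come from an iterative fit, so equality is to optimizer precision)
  off <- voltage_trace(g$trace$samples + 5, 100, "ca")
  fo <- extract_ca_transients(off)
  expect_equal(fo$ensemble$r_amp, f$ensemble$r_amp, tolerance = 1e-9)
  expect_equal(fo$ensemble$dca_rise_max, f$ensemble$dca_rise_max,
               tolerance = 1e-4)
  sc <- voltage_trace(3 * g$trace$samples, 100, "ca")
  fsc <- extract_ca_transients(sc)
  expect_equal(fsc$ensemble$r_amp, 3 * f$ensemble$r_amp, tolerance = 1e-9)
  expect_equal(fsc$ensemble$dca_decay_max, 3 * f$ensemble$dca_decay_max,
               tolerance = 1e-4)
})

test_that("kinetics recovery from the ensemble average is accurate", {
  for (s in c(2, 9, 17)) {
    g <- gen_ca_trace(duration_s = 40, seed = s)
    k <- estimate_ca_kinetics(extract_ca_transients(g$trace))
    expect_lt(abs(k$amplitude / 0.8 - 1), 0.05)
    expect_lt(abs(k$tau_rise_s / 0.15 - 1), 0.10)
    expect_lt(abs(k$tau_decay_s / 0.40 - 1), 0.10)
  }
})

test_that("caffeine response parameters follow their definitions", {
  g <- gen_ca_trace(duration_s = 60, caffeine_time_s = 30, f_caf = 2,
                    gap_s = 8, noise_frac = 0, seed = 3)
  r <- analyze_caffeine(g$trace, 30)
  expect_equal(r$amp_change_pct, 100, tolerance = 0.5)
  expect_equal(r$recovery_time_s, 8, tolerance = 0.05)
  expect_gt(r$area_fold_change, 1)

  # caffeine transient identical to the regular ones: fold change 1, no
  # amplitude change, recovery equal to the beat period
  gi <- gen_ca_trace(duration_s = 60, caffeine_time_s = 30, f_caf = 1,
                     gap_s = 1.5, tau_decay_caf_s = 0.40, noise_frac = 0,
                     seed = 1)
  ri <- analyze_caffeine(gi$trace, 30)
  expect_equal(ri$amp_change_pct, 0, tolerance = 0.5)
  expect_equal(ri$area_fold_change, 1, tolerance = 0.02)

  expect_error(analyze_caffeine(g$trace, 90), "inside")
  expect_error(analyze_caffeine(g$trace, 2), "pre-caffeine")

  # noisy recovery stays within the generator's gap
  gn <- gen_ca_trace(duration_s = 60, caffeine_time_s = 30, seed = 8)
  rn <- analyze_caffeine(gn$trace, 30)
  expect_equal(rn$recovery_time_s, 8, tolerance = 0.2)
})
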