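test_that("SD1/SD2/CV agree with the brute-force oracle to 1e-12", {
  set.seed(101)
  for (i in 1:25) {
    ibis <- runif(sample(10:200, 1), 0.4, 1.8)
    bs <- beat_series(cumsum(c(0, ibis)))
    b <- compute_brv(bs)
    o <- brute_brv(ibis)
    expect_equal(b$sd1_s, o$sd1, tolerance = 1e-12)
    expect_equal(b$sd2_s, o$sd2, tolerance = 1e-12)
    expect_equal(b$cv_pct, o$cv, tolerance = 1e-12)
    # identity sd1^2 + sd2^2 = 2 Var(IBI)
    expect_equal(b$sd1_s^2 + b$sd2_s^2, 2 * var(ibis), tolerance = 1e-12)
  }
})

test_that("closed-form Poincare cases", {
  const <- regular_beats(1.0, 50)
  b <- compute_brv(const)
  expect_equal(b$cv_pct, 0)
  expect_equal(b$sd1_s, 0)
  expect_equal(b$sd2_s, 0)

  # perfect alternation 0.5 / 0.7 s: SD1 = |delta| / sqrt(2), SD2 ~ 0
  ibis <- rep(c(0.5, 0.7), 100)
  ba <- compute_brv(beat_series(cumsum(c(0, ibis))))
  expect_equal(ba$sd1_s, 0.2 / sqrt(2), tolerance = 0.005)
  expect_lt(ba$sd2_s, 0.02)
  expect_equal(ba$cv_pct, 100 * 0.1 / 0.6, tolerance = 0.1)

  # i.i.d. IBIs: SD1 and SD2 both estimate sigma
  set.seed(9)
  ibis <- rnorm(1000, 0.6, 0.05)
  bi <- compute_brv(beat_series(cumsum(c(0, ibis))))
  expect_lt(abs(bi$sd1_s / 0.05 - 1), 0.10)
  expect_lt(abs(bi$sd2_s / 0.05 - 1), 0.10)

  expect_error(compute_brv(regular_beats(1, 3)), ">= 4 beats")
})

test_that("time rescaling scales SD1/SD2/mean and leaves CV unchanged", {
  set.seed(12)
  ibis <- runif(120, 0.5, 1.5)
  b1 <- compute_brv(beat_series(cumsum(c(0, ibis))))
  b2 <- compute_brv(beat_series(cumsum(c(0, 2.5 * ibis))))
  expect_equal(b2$mean_ibi_s, 2.5 * b1$mean_ibi_s, tolerance = 1e-12)
  expect_equal(b2$sd1_s, 2.5 * b1$sd1_s, tolerance = 1e-12)
  expect_equal(b2$sd2_s, 2.5 * b1$sd2_s, tolerance = 1e-12)
  expect_equal(b2$cv_pct, b1$cv_pct, tolerance = 1e-12)
})

test_that("bimodality detection separates the firing regimes", {
  expect_false(detect_bimodality(regular_beats(1.0, 60))$bimodal)

  b <- gen_ibi_series("bimodal", c(0.8, 1.6), 0.03, 400, seed = 7)
  r <- detect_bimodality(b)
  expect_true(r$bimodal)
  expect_equal(r$mode_estimates_s, c(0.8, 1.6), tolerance = 0.05 * 1.6)

  u <- gen_ibi_series("unimodal", 0.6, 0.02, 400, seed = 5)
  expect_false(detect_bimodality(u)$bimodal)
  expect_error(detect_bimodality(regular_beats(1, 10)), ">= 30")
})

test_that("Poincare cloud counts reflect the switching structure", {
  expect_equal(poincare_cloud_count(regular_beats(1.0, 60)), 1L)

  alt <- gen_ibi_series("bimodal", c(0.8, 1.6), 0.03, 300, seed = 4,
                        switch_prob = 1)
  expect_equal(poincare_cloud_count(alt), 2L)  # strict alternation: off-diagonal only

  four <- gen_ibi_series("bimodal", c(0.8, 1.6), 0.03, 400, seed = 7,
                         switch_prob = 0.5)
  expect_equal(poincare_cloud_count(four), 4L)
})
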