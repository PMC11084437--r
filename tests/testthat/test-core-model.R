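test_that("voltage_trace and beat_series enforce their invariants", {
  expect_error(voltage_trace(c(1, NA, 3), 100, "ap"), "index 2")
  expect_error(voltage_trace(1, 100, "ap"), "at least 2")
  expect_error(voltage_trace(c(1, 2), 0, "ap"), "rate_hz")
  tr <- voltage_trace(c(-70, -69), 10000, "ap", t0_s = 2)
  expect_equal(trace_times(tr), c(2, 2.0001))
  expect_equal(trace_duration(tr), 2e-4)

  expect_error(beat_series(c(1, 1, 2)), "strictly increasing")
  bs <- beat_series(c(0, 0.5, 1.2))
  expect_equal(bs$ibis_s, c(0.5, 0.7))
  expect_length(beat_series(numeric())$ibis_s, 0)
})

test_that("trace files round-trip bit-for-bit and reject bad input", {
  g <- gen_ap_train(rate_bpm = 60, duration_s = 2, seed = 1)
  p <- withr::local_tempfile(fileext = ".csv")
  write_trace(g$trace, p)
  back <- read_trace(p)
  expect_identical(back$samples, g$trace$samples)
  expect_identical(back$rate_hz, g$trace$rate_hz)
  expect_identical(back$modality, "ap")

  # 2-column CSV with declared metadata reads as-is
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# rate_hz=10000", "# units=mV", "# modality=ap",
               "time_s,value",
               paste(sprintf("%.4f", (0:999) / 1e4), rnorm(1000), sep = ",")),
             p2)
  tr <- read_trace(p2)
  expect_equal(tr$rate_hz, 10000)
  expect_length(tr$samples, 1000)

  # NaN row is a hard error naming the row
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# rate_hz=100", "# modality=ap", "time_s,value",
               "0,1", "0.01,NaN", "0.02,2"), p3)
  expect_error(read_trace(p3), "row 2")

  # missing rate_hz is a hard error
  p4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# modality=ap", "time_s,value", "0,1", "0.01,2"), p4)
  expect_error(read_trace(p4), "rate_hz")

  expect_error(read_trace(p, format = "hdf5"), "not supported")
})

test_that("write_results appends a mean +/- SD summary and round-trips rows", {
  tab <- cohort_table(data.frame(group = "a", value = c(1, 2, 3)))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_results(tab, p)
  lines <- readLines(p)
  summ <- grep("^# a value", lines, value = TRUE)
  parts <- strsplit(summ, " ")[[1]]
  expect_equal(as.numeric(parts[4]), 2)   # mean
  expect_equal(as.numeric(parts[5]), 1)   # sample SD
  back <- read_results(p)
  expect_equal(back$value, c(1, 2, 3))

  expect_error(write_results(cohort_table(data.frame(group = character(),
                                                     value = numeric())), p),
               "empty")
  two <- cohort_table(data.frame(group = c("a", "a", "a"), value = 1:3),
                      groups = c("a", "b"))
  expect_error(write_results(two, p), "empty group")
})

test_that("cohort_table validates groups and feature types", {
  expect_error(cohort_table(data.frame(x = 1)), "group")
  expect_error(cohort_table(data.frame(group = "a", f = "txt")), "non-numeric")
  expect_error(cohort_table(data.frame(group = "c", f = 1), groups = c("a", "b")),
               "outside")
})
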