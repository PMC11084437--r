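test_that("segmentation reproduces the ground-truth masks", {
  g <- gen_cell_image(nc_ratio = 1.0, noise_frac = 0, seed = 1)
  m <- segment_cell(g$pair, 50, 10)
  expect_identical(m$nucleus, g$truth$nucleus_mask)
  expect_identical(m$cell, g$truth$cell_mask)
  expect_identical(m$cytoplasm, g$truth$cytoplasm_mask)

  # under 5% noise the nucleus area is recovered within 2%
  gn <- gen_cell_image(nc_ratio = 1.3, noise_frac = 0.05, seed = 2)
  mn <- segment_cell(gn$pair, 50, 10)
  expect_lt(abs(sum(mn$nucleus) / sum(gn$truth$nucleus_mask) - 1), 0.02)

  zero <- structure(list(nuclear = matrix(0, 32, 32),
                         signal = matrix(0, 32, 32)),
                    class = "cell_image_pair")
  expect_error(segment_cell(zero, 10, 10), "empty")
})

test_that("N/C density ratio follows its definition and invariances", {
  g <- gen_cell_image(nc_ratio = 2.0, noise_frac = 0, seed = 1)
  m <- segment_cell(g$pair, 50, 10)
  r <- measure_nc_ratio(g$pair, m)
  expect_equal(r$nc_ratio, 2.0, tolerance = 1e-9)
  expect_equal(r$density_n, r$raw_int_den_nucleus / r$area_nucleus_px)

  # scale invariance of the ratio
  sc <- structure(list(nuclear = g$pair$nuclear, signal = 7.3 * g$pair$signal),
                  class = "cell_image_pair")
  expect_equal(measure_nc_ratio(sc, m)$nc_ratio, r$nc_ratio, tolerance = 1e-9)

  # RawIntDen additivity over disjoint splits
  half <- m$cytoplasm
  half[, seq_len(ncol(half) / 2)] <- FALSE
  other <- m$cytoplasm & !half
  expect_equal(sum(g$pair$signal[half]) + sum(g$pair$signal[other]),
               r$raw_int_den_cytoplasm)
})

test_that("generator N/C ratios are recovered within 5% under noise", {
  for (nc in c(0.25, 1.30)) {
    g <- gen_cell_image(nc_ratio = nc, noise_frac = 0.05, seed = 11)
    m <- segment_cell(g$pair, 50, 10)
    expect_lt(abs(measure_nc_ratio(g$pair, m)$nc_ratio / nc - 1), 0.05)
  }
  # poisson noise model
  gp <- gen_cell_image(nc_ratio = 2.66, noise_model = "poisson", seed = 4)
  mp <- segment_cell(gp$pair, 50, 10)
  expect_lt(abs(measure_nc_ratio(gp$pair, mp)$nc_ratio / 2.66 - 1), 0.05)
})

test_that("cohort summaries aggregate mean, sample SD and n per group", {
  s <- cohort_nc_summary(c(1, 2, 3), rep("a", 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$n, 3L)
  expect_warning(cohort_nc_summary(c(1, NA), c("a", "b")), "skipped")
})

test_that("image pairs round-trip through PNG files", {
  skip_if_not_installed("png")
  g <- gen_cell_image(nc_ratio = 1.3, seed = 5, mean_intensity = 0.3,
                      nuc_channel_intensity = 0.5, noise_frac = 0)
  d <- withr::local_tempdir()
  np <- file.path(d, "nuc.png"); sp <- file.path(d, "sig.png")
  png::writePNG(g$pair$nuclear, np)
  png::writePNG(g$pair$signal, sp)
  pair <- read_image_pair(np, sp)
  expect_equal(dim(pair$signal), dim(g$pair$signal))
  m <- segment_cell(pair, 0.25, 0.05)
  # PNG stores 8-bit samples; quantization moves the ratio by ~1%
  expect_equal(measure_nc_ratio(pair, m)$nc_ratio, 1.3, tolerance = 0.02)
})
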