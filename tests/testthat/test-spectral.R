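# The three built-in presets, frozen here as an independent transcription of
# the published period-range tables.
expected_presets <- list(
  DANIO_XENOPUS_18 = matrix(c(
    598, 298, 200, 149, 120, 99, 85, 54, 49, 33, 29, 20.5, 21, 17, 16, 15,
    14, 13, 12, 11, 10, 5, 4.9, 3.5, 3.3, 2.5, 2.4, 1.7, 1.6, 1, 0.9, 0.33,
    0.3, 0.25, 0.24, 0.1), ncol = 2, byrow = TRUE),
  RADIX_STAGE_18 = matrix(c(
    598, 299, 291, 145, 120, 100, 85, 75, 66, 60, 54, 50, 46, 43, 40, 37,
    35, 30, 29, 24, 20, 17, 15, 12.5, 12.2, 10, 9.5, 5, 2, 1.1, 1, 0.68,
    0.66, 0.5, 0.3, 0.26), ncol = 2, byrow = TRUE),
  RADIX_STRESSOR_30 = matrix(c(
    300, 150, 100, 75, 60, 50, 43, 37.5, 33.5, 30, 27.5, 25, 23, 21.5,
    20, 19, 17.5, 16.5, 16, 14.5, 13.5, 12.5, 12, 11, 10.5, 9.5, 9, 6.5,
    6.3, 5, 4.9, 3.5, 3.3, 2.5, 2.4, 2, 1.9, 1.5, 1.4, 1, 0.9, 0.8,
    0.7, 0.65, 0.6, 0.5, 0.49, 0.4, 0.39, 0.34, 0.33, 0.28, 0.27, 0.22,
    0.21, 0.18, 0.17, 0.15, 0.14, 0.13), ncol = 2, byrow = TRUE)
)

test_that("built-in presets match the published bin tables bin for bin", {
  for (nm in names(expected_presets)) {
    bs <- preset(nm)
    expect_equal(unname(bs$bins), expected_presets[[nm]], label = nm)
  }
  expect_length(preset("DANIO_XENOPUS_18"), 18)
  expect_length(preset("RADIX_STAGE_18"), 18)
  expect_length(preset("RADIX_STRESSOR_30"), 30)
  expect_error(preset("bogus"), "DANIO_XENOPUS_18")
})

test_that("binset validation enforces ordering and positivity", {
  expect_error(frequency_binset(rbind(c(5, 10))), "period_hi_s > period_lo_s")
  expect_error(frequency_binset(rbind(c(5, 2), c(10, 6))), "decreasing")
  expect_error(frequency_binset(rbind(c(5, 0))), "positive")
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("name: custom2", "bins:", "  - [10, 5]", "  - [4, 2]"), tmp)
  bs <- read_binset(tmp)
  expect_equal(unname(bs$bins), rbind(c(10, 5), c(4, 2)))
})

test_that("the DFT energy spectrum matches the closed form for on-grid sinusoids", {
  fps <- 7.5; n <- 600 * fps
  t <- (seq_len(n) - 1) / fps
  sp <- dft_energy_spectrum(sin(2 * pi * t / 10), fps)
  hit <- which(sp$energies > 1e-12)
  expect_length(hit, 1)
  expect_equal(sp$periods_s[hit], 10)
  expect_equal(sp$energies[hit], 0.5, tolerance = 1e-9)
  # two disjoint on-grid sinusoids: energies add component-wise
  s2 <- 2 * sin(2 * pi * t / 30)
  both <- dft_energy_spectrum(sin(2 * pi * t / 10) + s2, fps)
  hits <- which(both$energies > 1e-9)
  expect_setequal(round(both$periods_s[hits], 9), c(10, 30))
  expect_equal(sum(both$energies), 0.5 + 0.5 * 4, tolerance = 1e-9)
  # constant series has no energy anywhere
  expect_equal(max(dft_energy_spectrum(rep(3.2, 100), fps)$energies), 0)
  expect_error(dft_energy_spectrum(c(1, 2, 3), fps), "insufficient samples")
})

test_that("spectrum periods run from N/fps down to the two-sample period", {
  sp <- dft_energy_spectrum(rnorm(4500), 7.5)
  expect_equal(max(sp$periods_s), 600)
  expect_equal(min(sp$periods_s), 2 / 7.5)
  expect_true(all(diff(sp$periods_s) < 0))
})

test_that("a 10 s sinusoid lands entirely in the 10-5 s bin of the 18-bin preset", {
  fps <- 7.5; t <- (0:4499) / fps
  sp <- dft_energy_spectrum(sin(2 * pi * t / 10), fps)
  b <- bin_energies(sp, preset("DANIO_XENOPUS_18"))
  expect_equal(b[11], 0.5, tolerance = 1e-9)
  expect_lt(sum(b[-11]), 1e-12)
})

test_that("binning conserves total energy on a gap-free binset (Parseval)", {
  set.seed(10)
  for (i in 1:20) {
    n <- sample(50:400, 1)
    fps <- sample(c(7.5, 15), 1)
    sp <- dft_energy_spectrum(rnorm(n), fps)
    bs <- full_cover_binset(n, fps, nbins = sample(3:10, 1))
    expect_equal(sum(bin_energies(sp, bs)), sum(sp$energies),
                 tolerance = 1e-9)
  }
})

test_that("coefficients on an overlap are counted once, in the longer-period bin", {
  fps <- 1; n <- 100
  sp <- dft_energy_spectrum(sin(2 * pi * (0:(n - 1)) / 10), fps)  # period 10 s
  overlapping <- frequency_binset(rbind(c(20, 10), c(10.5, 5)))
  b <- bin_energies(sp, overlapping)
  expect_equal(b[1], 0.5, tolerance = 1e-9)
  expect_equal(b[2], 0)
})

test_that("feature vectors concatenate the four series in fixed order", {
  rec <- random_motion_record(n = 200, seed = 2)
  fv <- assemble_features(rec, preset("DANIO_XENOPUS_18"))
  expect_length(fv$values, 72)
  expect_equal(names(fv$values)[1], "pos_angle.bin01")
  expect_equal(names(fv$values)[19], "neg_angle.bin01")
  expect_equal(names(fv$values)[37], "com_rho.bin01")
  expect_equal(names(fv$values)[55], "com_theta.bin01")
  fv30 <- assemble_features(rec, preset("RADIX_STRESSOR_30"))
  expect_length(fv30$values, 120)
  # the pos_angle block equals binning that series directly
  direct <- bin_energies(dft_energy_spectrum(rec$pos_angle, rec$fps),
                         preset("DANIO_XENOPUS_18"))
  expect_equal(unname(fv$values[1:18]), log(direct + 1))
  # all-zero record maps to the zero vector under log(x+1)
  z <- rep(0, 16)
  zero_rec <- motion_record(z, z, z, z, fps = 7.5)
  expect_equal(max(assemble_features(zero_rec, preset("RADIX_STAGE_18"))$values), 0)
})

test_that("bin values scale as amplitude squared and ignore circular shifts", {
  set.seed(11)
  bs <- preset("RADIX_STAGE_18")
  for (i in 1:5) {
    x <- rnorm(300)
    b1 <- bin_energies(dft_energy_spectrum(x, 7.5), bs)
    b2 <- bin_energies(dft_energy_spectrum(3 * x, 7.5), bs)
    expect_equal(b2, 9 * b1, tolerance = 1e-9)
    expect_true(all(b2 >= b1 - 1e-12))
    sh <- c(x[101:300], x[1:100])
    b3 <- bin_energies(dft_energy_spectrum(sh, 7.5), bs)
    expect_equal(b3, b1, tolerance = 1e-9)
  }
})

test_that("feature matrices round-trip through CSV with ids and names", {
  recs <- lapply(1:3, function(s) random_motion_record(n = 120, seed = s))
  fv <- lapply(recs, assemble_features, binset = preset("RADIX_STAGE_18"))
  m <- feature_matrix(fv)
  expect_equal(dim(m), c(3, 72))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(m, tmp)
  back <- read_feature_csv(tmp)
  expect_equal(rownames(back), rownames(m))
  expect_equal(unname(back), unname(m), tolerance = 1e-12)
})
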