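test_that("class spectra are smooth, bounded, and monotone in separation", {
  s0 <- make_class_spectra(64, 0, seed = 3)
  expect_identical(s0$tumor, s0$normal)

  seps <- c(0, 0.05, 0.1, 0.2, 0.4)
  mads <- vapply(seps, function(s) {
    sp <- make_class_spectra(64, s, seed = 3)
    expect_true(all(sp$tumor >= 0 & sp$tumor <= 1))
    expect_true(all(sp$normal >= 0 & sp$normal <= 1))
    mean(abs(sp$tumor - sp$normal))
  }, numeric(1))
  expect_true(all(diff(mads) >= 0))

  expect_identical(make_class_spectra(32, 0.2, seed = 9),
                   make_class_spectra(32, 0.2, seed = 9))
  expect_error(make_class_spectra(32, -0.1), "separation")
  expect_error(make_class_spectra(1, 0.1), "n_bands")
})

test_that("the noiseless phantom reproduces the class means exactly", {
  spec <- phantom_spec(height = 24, width = 24, n_bands = 8, noise_sd = 0,
                       illumination_amplitude = 0, vessel_density = 0,
                       margin_px = 0, seed = 4)
  ph <- generate_phantom(spec)
  tum <- which(ph$mask$mask == 1L)
  nor <- which(ph$mask$mask == 0L)
  for (b in seq_len(8)) {
    plane <- ph$cube$data[, , b]
    expect_true(all(plane[tum] == ph$spectra$tumor[b]))
    expect_true(all(plane[nor] == ph$spectra$normal[b]))
  }
})

test_that("phantom masks are binary, 4-connected, and near the target area", {
  for (seed in 1:6) {
    ph <- generate_phantom(phantom_spec(tumor_fraction = 0.2, seed = seed))
    m <- ph$mask$mask
    expect_true(all(m %in% c(0L, 1L)))
    lab <- label_components(m, connectivity = 4)
    expect_identical(max(lab), 1L)
    # +/- 20% of 0.2 * 64 * 64 = [655, 983], counted on the output
    expect_gte(sum(m), 655)
    expect_lte(sum(m), 983)
  }
})

test_that("phantom cubes stay in [0, 1] with all confounders active", {
  ph <- generate_phantom(phantom_spec(noise_sd = 0.08,
                                      illumination_amplitude = 0.4,
                                      vessel_density = 6, seed = 21))
  expect_gte(min(ph$cube$data), 0)
  expect_lte(max(ph$cube$data), 1)
})

test_that("cohorts are reproducible, varied, and share class spectra", {
  spec <- phantom_spec(height = 24, width = 24, n_bands = 8)
  a <- generate_cohort(12, spec, seed = 5)
  b <- generate_cohort(12, spec, seed = 5)
  expect_identical(a, b)
  masks <- lapply(a, function(s) s$mask$mask)
  expect_identical(length(unique(masks)), 12L)
  spectra <- lapply(a, `[[`, "spectra")
  expect_identical(length(unique(spectra)), 1L)

  c2 <- generate_cohort(3, spec, seed = 6)
  expect_false(identical(a[[1]]$cube$data, c2[[1]]$cube$data))
  expect_error(generate_cohort(1, spec), "n_samples")
})

test_that("cohorts round-trip through the on-disk manifest", {
  td <- withr::local_tempdir()
  cohort <- generate_cohort(3, phantom_spec(height = 12, width = 12,
                                            n_bands = 4), seed = 2)
  mp <- write_cohort(cohort, td)
  back <- read_cohort(mp)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_identical(back[[i]]$cube$data, cohort[[i]]$cube$data)
    expect_identical(back[[i]]$mask$mask, cohort[[i]]$mask$mask)
  }
})

test_that("a linear fit separates well-separated phantom spectra but not sep-0", {
  fx <- separable_fixture()
  ld <- MASS::lda(fx$pool$x, grouping = fx$pool$y)
  expect_gte(mean(predict(ld)$class == fx$pool$y), 0.99)

  ph0 <- generate_phantom(phantom_spec(separation = 0, tumor_fraction = 0.5,
                                       vessel_density = 0, margin_px = 0,
                                       seed = 31))
  pool0 <- adapthsi:::pooled_spectra(list(ph0$cube), list(ph0$mask), 1500, 1)
  ld0 <- MASS::lda(pool0$x, grouping = pool0$y)
  expect_lte(mean(predict(ld0)$class == pool0$y), 0.65)
})
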