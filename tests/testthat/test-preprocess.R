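test_that("spot diameter follows the Rayleigh formula", {
  expect_equal(round(spot_diameter(532, 0.90)), 721)
  expect_equal(spot_diameter(500, 0.5), 1220)
  # doubling the numerical aperture halves the diameter
  expect_equal(spot_diameter(600, 0.4), 2 * spot_diameter(600, 0.8))
  expect_error(spot_diameter(-1, 0.9))
  expect_error(spot_diameter(532, 0))
})

test_that("axis calibration is a rigid translation with a sanity bound", {
  s <- raman_spectrum(600:700, stats::rnorm(101))
  expect_identical(calibrate_axis(s, 520.7)$shifts, s$shifts)
  s2 <- calibrate_axis(s, 522.7)
  expect_equal(s2$shifts, s$shifts - 2)
  expect_identical(s2$intensities, s$intensities)
  back <- calibrate_axis(s2, 518.7)
  expect_equal(back$shifts, s$shifts)
  expect_error(calibrate_axis(s, 535), "offset")
})

test_that("background subtraction interpolates onto the sample grid", {
  s <- raman_spectrum(600:800, stats::rnorm(201) + 5)
  zero <- raman_spectrum(c(500, 900), c(0, 0))
  expect_equal(subtract_background(s, zero)$intensities, s$intensities)
  self <- raman_spectrum(s$shifts, s$intensities)
  expect_equal(subtract_background(s, self)$intensities, rep(0, 201))

  # coarse background vs an independently coded linear interpolant
  coarse_x <- seq(550, 850, by = 25)
  coarse_y <- 0.002 * (coarse_x - 550)^1.3
  bg <- raman_spectrum(coarse_x, coarse_y)
  out <- subtract_background(s, bg)
  manual <- vapply(s$shifts, function(x) {
    i <- max(which(coarse_x <= x))
    if (coarse_x[i] == x) return(coarse_y[i])
    w <- (x - coarse_x[i]) / (coarse_x[i + 1] - coarse_x[i])
    (1 - w) * coarse_y[i] + w * coarse_y[i + 1]
  }, numeric(1))
  expect_equal(out$intensities, s$intensities - manual, tolerance = 1e-12)

  narrow <- raman_spectrum(c(650, 750), c(1, 1))
  expect_error(subtract_background(s, narrow), "cover")
})

test_that("baseline correction is exact on peak-free polynomial inputs", {
  x <- seq(600, 1800, by = 2)
  u <- (x - 600) / 1200
  cubic <- 2 + 0.8 * u - 1.5 * u^2 + 0.9 * u^3
  s <- raman_spectrum(x, cubic)
  out <- baseline_correct(s)
  expect_lt(max(abs(out$intensities)), 1e-6 * max(abs(cubic)))
  flat <- baseline_correct(raman_spectrum(x, rep(3, length(x))))
  expect_lt(max(abs(flat$intensities)), 1e-8)
})

test_that("baseline correction recovers known peaks under a known cubic", {
  x <- seq(600, 1800, by = 2)
  u <- (x - 600) / 1200
  peaks <- 0.9 * exp(-(x - 1004)^2 / 50) + 0.6 * exp(-(x - 1440)^2 / 120) +
    0.4 * exp(-(x - 784)^2 / 80)
  cubic <- 1.5 + u - 0.7 * u^2 + 0.4 * u^3
  out <- baseline_correct(raman_spectrum(x, peaks + cubic))
  expect_gt(stats::cor(out$intensities, peaks), 0.99)
})

test_that("vector normalization scales to unit L2 norm and is idempotent", {
  s <- raman_spectrum(c(600, 601), c(3, 4))
  expect_equal(vector_normalize(s)$intensities, c(0.6, 0.8))
  r <- raman_spectrum(600:650, stats::rnorm(51))
  n1 <- vector_normalize(r)
  expect_equal(sum(n1$intensities^2), 1, tolerance = 1e-12)
  expect_equal(vector_normalize(n1)$intensities, n1$intensities)
  expect_error(vector_normalize(raman_spectrum(600:610, rep(0, 11))), "zero")
})

test_that("the pipeline enforces its postconditions on every spectrum", {
  empty <- raman_set(tiny_axis(), matrix(0, 0, length(tiny_axis())))
  expect_equal(n_spectra(preprocess_spectra(empty)), 0)

  cfg <- sim_config(n_cells_per_class = 4, axis = seq(550, 1900, by = 4),
                    seed = 2)
  raw <- generate_dataset(cfg)
  bg <- raman_spectrum(seq(500, 2000, by = 10),
                       0.3 + 0.0001 * seq(500, 2000, by = 10))
  pp <- preprocess_spectra(raw, bg = bg, measured_si_line = 521.2)
  expect_true(all(pp$meta$stage == "preprocessed"))
  expect_true(all(abs(rowSums(pp$intensities^2) - 1) < 1e-10))
  expect_true(min(pp$shifts) >= 600 && max(pp$shifts) <= 1800)
  expect_error(preprocess_spectra(pp), "raw")
})

test_that("preprocessing preserves the simulated class difference signs", {
  cfg <- sim_config(n_cells_per_class = 20, axis = tiny_axis(),
                    noise_sd = 0.01, cell_effect_sd = 0.05, seed = 31)
  pp <- preprocess_spectra(generate_dataset(cfg))
  labs <- set_labels(pp)
  d <- colMeans(pp$intensities[labs == "Tumor", ]) -
    colMeans(pp$intensities[labs == "Non-Tumor", ])
  b <- default_band_table()
  for (cc in b$center[b$tumor_multiplier > 1])
    expect_gt(d[which.min(abs(pp$shifts - cc))], 0)
  for (cc in b$center[b$tumor_multiplier < 1])
    expect_lt(d[which.min(abs(pp$shifts - cc))], 0)
})
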