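test_that("pure spectra are Gaussian band sums", {
  g <- wn_grid(7000, 9000, 100)
  a1 <- analyte_spec("x", data.frame(center = 8000, width = 100,
                                     amplitude = 1),
                     plateau_conc = 1, start_conc = 1.5,
                     decay_rate = 0.1)
  eps <- pure_spectrum(a1, g)
  expect_equal(eps[g$points == 8000], 1.0)
  expect_equal(eps[g$points == 8100], exp(-0.5))
  # linearity: two identical bands double the profile
  a2 <- analyte_spec("x2", data.frame(center = c(8000, 8000),
                                      width = c(100, 100),
                                      amplitude = c(1, 1)),
                     1, 1.5, 0.1)
  expect_equal(pure_spectrum(a2, g), 2 * eps)
  expect_error(analyte_spec("bad", data.frame()[0, ], 1, 1, 0.1),
               "no bands")
})

test_that("wavenumber grid invariants hold", {
  g <- wn_grid(4000, 12000, 8)
  expect_length(g$points, 1001)
  expect_true(all(diff(g$points) > 0))
  expect_error(wn_grid(5000, 4000, 8), "start")
  expect_error(wn_grid(4000, 12000, 0), "step")
})

test_that("concentration trajectory follows dilution then first-order decay", {
  cfg <- study_config(initial_volume = 100, water_flow = 1,
                      water_add_duration = 30)
  an <- analyte_spec("x", data.frame(center = 8000, width = 100,
                                     amplitude = 1),
                     plateau_conc = 0.8, start_conc = 1.3,
                     decay_rate = 0.05)
  # dilution value at the phase boundary
  expect_equal(trajectory(an, cfg, 0), 1.3 * 100 / 130)
  # no dilution when water flow is zero
  cfg0 <- study_config(water_flow = 0)
  expect_equal(trajectory(an, cfg0, c(-30, -10, -0.5)), rep(1.3, 3))
  # plateau equal to c(0-) is a fixed point of the relaxation
  c0 <- 1.3 * 100 / 130
  an2 <- analyte_spec("x", an$bands, plateau_conc = c0,
                      start_conc = 1.3, decay_rate = 0.05)
  expect_equal(trajectory(an2, cfg, seq(0, 100, 10)), rep(c0, 11))
  # continuity at t = 0 and positivity
  tt <- seq(-30, 100, 0.5)
  cc <- trajectory(an, cfg, tt)
  expect_true(all(cc > 0))
  i0 <- which(tt == 0)
  expect_equal(cc[i0 - 1], cc[i0], tolerance = 1e-2)
  expect_error(trajectory(an, cfg, c(-40, 0)), "outside")
})

test_that("batch synthesis is deterministic and Beer-Lambert linear without noise", {
  cfg <- small_config()
  b1 <- synthesize_batch(cfg, 2)
  b2 <- synthesize_batch(cfg, 2)
  expect_identical(b1$spectra$A, b2$spectra$A)
  expect_identical(b1$reference, b2$reference)
  expect_false(identical(b1$spectra$A, synthesize_batch(cfg, 3)$spectra$A))

  # noise off, no water, no batch variation: A is exactly linear in c
  clean <- small_config(
    noise = noise_model(0, 0, 0, 0, 1),
    water_bands = data.frame(center = 5200, width = 150, amplitude = 0),
    batch_scale_sigma = 0)
  b <- synthesize_batch(clean, 2)
  eps <- vapply(clean$analytes, pure_spectrum,
                numeric(length(clean$grid$points)), grid = clean$grid)
  conc <- vapply(clean$analytes, trajectory,
                 numeric(length(b$spectra$t_min)),
                 cfg = clean, times = b$spectra$t_min)
  expect_equal(b$spectra$A, conc %*% t(eps), tolerance = 1e-12)

  # doubling all concentrations doubles the spectra channel-wise
  doubled <- clean
  doubled$analytes <- lapply(clean$analytes, function(a) {
    a$start_conc <- 2 * a$start_conc
    a$plateau_conc <- 2 * a$plateau_conc
    a
  })
  expect_equal(synthesize_batch(doubled, 2)$spectra$A, 2 * b$spectra$A,
               tolerance = 1e-12)
})

test_that("reference rows equal trajectory values at the reference cadence", {
  cfg <- small_config(batch_scale_sigma = 0)
  b <- synthesize_batch(cfg, 3)
  expect_equal(b$reference$t_min, seq(-10, 20, by = 2))
  for (an in names(cfg$analytes))
    expect_equal(b$reference[[an]],
                 trajectory(cfg$analytes[[an]], cfg, b$reference$t_min))
})

test_that("water bands saturate the detector inside 4600-5450 cm-1", {
  cfg <- study_config(water_bands = data.frame(
    center = c(5200, 6900), width = c(150, 300), amplitude = c(2, 2)))
  b <- synthesize_batch(cfg, 2)
  win <- cfg$grid$points >= 4600 & cfg$grid$points <= 5450
  expect_true(all(apply(b$spectra$A[, win], 1, max) > 1.5))
})

test_that("study roles follow the pre/calibration/validation design", {
  st <- simulate_study(small_config())
  expect_identical(st$roles, c("pre", "cal", "cal", "cal", "val"))
  expect_warning(st2 <- simulate_study(small_config(n_batches = 2)),
                 "calibration set is empty")
  expect_identical(st2$roles, c("pre", "val"))
  expect_error(simulate_study(small_config(n_batches = 1)))
  # reference sample count per batch follows the cadences
  cfg <- small_config()
  n_ref <- nrow(st$batches[[1]]$reference)
  expect_equal(n_ref, (cfg$water_add_duration + cfg$thermostat_duration) /
                 cfg$reference_cadence + 1)
})

test_that("invalid configurations are rejected with the violated invariant", {
  expect_error(study_config(reference_cadence = 0.7, spectra_cadence = 0.5),
               "integer multiple")
  expect_error(study_config(thermostat_duration = -1), "thermostat")
  expect_error(noise_model(scatter_sigma = -1), "sigmas")
  expect_error(noise_model(waterband_noise_factor = 0.5), "factor")
})
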