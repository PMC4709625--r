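test_that("pretreatment screening recovers exact models on clean data", {
  clean <- small_config(noise = noise_model(0, 0, 0, 0, 1),
                        batch_scale_sigma = 0.02)
  st <- simulate_study(clean)
  tab <- compare_pretreatments(
    st, pretreats = standard_pretreatments()[c("raw", "der1")],
    max_lv = 4)
  ok <- !tab$failed
  expect_true(all(tab$r2_pct[ok] > 99.9))
  expect_equal(sum(tab$chosen), length(unique(tab$analyte)))
})

test_that("derivative pretreatment beats raw spectra under baseline drift", {
  drift <- small_config(
    noise = noise_model(scatter_sigma = 0,
                        baseline_offset_sigma = 0.05,
                        baseline_slope_sigma = 5e-5,
                        noise_floor = 5e-4,
                        waterband_noise_factor = 2),
    base_seed = 7)
  st <- simulate_study(drift)
  # with the component budget at the chemical rank, the raw models must
  # spend latent variables on the rank-2 baseline subspace while the
  # derivative removes it outright
  tab <- compare_pretreatments(
    st, pretreats = standard_pretreatments()[c("raw", "der1")],
    max_lv = 4)
  for (an in unique(tab$analyte)) {
    raw_cv <- tab$rmsecv[tab$pretreatment == "raw" & tab$analyte == an]
    der_cv <- tab$rmsecv[tab$pretreatment == "der1" & tab$analyte == an]
    expect_lt(der_cv, raw_cv)
  }
})

test_that("the workflow is deterministic in (config, seed)", {
  cfg <- small_config(base_seed = 99)
  c1 <- nir_calibrate(simulate_study(cfg), max_lv = 5)
  c2 <- nir_calibrate(simulate_study(cfg), max_lv = 5)
  expect_identical(c1$metrics, c2$metrics)
  expect_identical(c1$models$DSS$pls$coefficients,
                   c2$models$DSS$pls$coefficients)
})

test_that("calibration artifacts do not depend on the validation batch", {
  cfg <- small_config(base_seed = 5)
  st <- simulate_study(cfg)
  st2 <- st
  # corrupt the validation batch wholesale
  st2$batches[[5]]$spectra$A <- st2$batches[[5]]$spectra$A * 2 + 1
  for (an in names(cfg$analytes))
    st2$batches[[5]]$reference[[an]] <-
      st2$batches[[5]]$reference[[an]] * 3
  c1 <- nir_calibrate(st, max_lv = 5)
  c2 <- nir_calibrate(st2, max_lv = 5)
  for (an in names(cfg$analytes)) {
    expect_identical(c1$models[[an]]$pls$coefficients,
                     c2$models[[an]]$pls$coefficients)
    expect_identical(c1$models[[an]]$pretreat$state,
                     c2$models[[an]]$pretreat$state)
    expect_identical(c1$models[[an]]$channels$index,
                     c2$models[[an]]$channels$index)
  }
})

test_that("a validation batch equal to a calibration batch gives RMSEP ~ RMSEC", {
  st <- simulate_study(small_config(base_seed = 11))
  dup <- st$batches[[2]]
  dup$role <- "val"; dup$reference$role <- "val"
  st$batches[[5]] <- dup
  cal <- nir_calibrate(st, max_lv = 5)
  expect_true(all(cal$metrics$rmsep < 2 * cal$metrics$rmsec))
})

test_that("a single latent variable underfits the four-analyte mixture", {
  st <- simulate_study(small_config(base_seed = 3))
  full <- nir_calibrate(st, max_lv = 6)
  lv1 <- nir_calibrate(st, max_lv = 1)
  expect_true(all(lv1$metrics$rsep > full$metrics$rsep))
})

test_that("streaming prediction matches batch prediction record by record", {
  st <- simulate_study(small_config(base_seed = 13))
  cal <- nir_calibrate(st, max_lv = 5)
  val <- st$batches[[5]]
  mon <- monitor_stream(cal, val$spectra, reference = val$reference)
  expect_equal(nrow(mon$records), nrow(val$spectra$A))
  batch_pred <- predict(cal, val$spectra)
  for (an in names(cal$models))
    expect_equal(mon$records[[an]], unname(batch_pred[, an]))
  # summary agrees with the calibration's validation metrics
  expect_equal(mon$summary$rsep,
               cal$metrics$rsep[match(mon$summary$analyte,
                                      cal$metrics$analyte)],
               tolerance = 1e-10)
  expect_true(all(mon$records$error == ""))
})

test_that("control limits flag nothing for an in-range trajectory", {
  cfg <- small_config(batch_scale_sigma = 0)
  # trajectories whose whole course stays inside plateau +/- 20%
  cfg$analytes <- lapply(cfg$analytes, function(a) {
    dil <- (cfg$initial_volume + cfg$water_flow * cfg$water_add_duration) /
      cfg$initial_volume
    a$start_conc <- a$plateau_conc * 1.05 * dil
    a
  })
  st <- simulate_study(cfg)
  cal <- nir_calibrate(st, max_lv = 5)
  mon <- monitor_stream(cal, st$batches[[5]]$spectra,
                        control_limits = default_control_limits(cfg))
  expect_equal(mon$n_flagged, 0)
  # a grid mismatch produces record-level errors but no crash
  bad <- st$batches[[5]]$spectra
  bad$A <- bad$A[, 1:100]
  bad$wavenumber <- bad$wavenumber[1:100]
  mon2 <- monitor_stream(cal, bad)
  expect_equal(sum(mon2$records$error != ""), nrow(bad$A))
})

test_that("spectra, reference and model files round-trip", {
  st <- simulate_study(small_config(base_seed = 17))
  d <- withr::local_tempdir()
  sp <- st$batches[[2]]$spectra
  write_spectra(sp, file.path(d, "sp.csv"))
  back <- read_spectra(file.path(d, "sp.csv"))
  expect_equal(back$A, sp$A)
  expect_equal(back$t_min, sp$t_min)
  expect_equal(back$wavenumber, sp$wavenumber)

  refs <- st$batches[[2]]$reference
  write_references(refs, file.path(d, "ref.csv"))
  expect_equal(read_references(file.path(d, "ref.csv"),
                               analytes = names(st$config$analytes))$DSS,
               refs$DSS)
  expect_error(read_references(file.path(d, "ref.csv"),
                               analytes = "XYZ"),
               "missing column\\(s\\): XYZ")

  # non-monotonic wavenumber column is rejected with a line number
  bad <- utils::read.csv(file.path(d, "sp.csv"), check.names = FALSE)
  bad[2, 1] <- bad[1, 1]
  utils::write.csv(bad, file.path(d, "bad.csv"), row.names = FALSE)
  expect_error(read_spectra(file.path(d, "bad.csv")), "non-monotonic")

  cal <- nir_calibrate(st, max_lv = 4)
  save_model(cal, file.path(d, "models.json"))
  models <- load_model(file.path(d, "models.json"))
  X <- st$batches[[5]]$spectra$A
  for (an in names(cal$models))
    expect_equal(predict(models[[an]], X), predict(cal$models[[an]], X),
                 tolerance = 1e-12)
  # save(load(save)) is bit-identical
  save_model(cal$models$DSS, file.path(d, "one.json"))
  m1 <- load_model(file.path(d, "one.json"))
  save_model(m1$DSS, file.path(d, "one2.json"))
  expect_identical(readLines(file.path(d, "one.json")),
                   readLines(file.path(d, "one2.json")))
})

test_that("YAML study configurations round-trip field for field", {
  cfg <- small_config(base_seed = 23)
  d <- withr::local_tempdir()
  write_study_config(cfg, file.path(d, "cfg.yaml"))
  back <- read_study_config(file.path(d, "cfg.yaml"))
  expect_equal(back$grid$points, cfg$grid$points)
  expect_equal(back$analytes$PA$bands, cfg$analytes$PA$bands)
  expect_equal(unclass(back$noise), unclass(cfg$noise))
  expect_equal(back$base_seed, cfg$base_seed)
  # identical synthetic output from the round-tripped config
  expect_identical(synthesize_batch(back, 2)$spectra$A,
                   synthesize_batch(cfg, 2)$spectra$A)
})
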