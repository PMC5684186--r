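test_that("the analyte signature is the configured Gaussian peak sum", {
  cfg <- phantom_config(
    n_bands = 100L, wavelength_start_nm = 1000, wavelength_step_nm = 10,
    analyte_peaks = data.frame(center_nm = c(1300, 1700),
                               width_nm = c(40, 60),
                               amplitude = c(1, 0.5)),
    analyte_strength = 1)
  sig <- make_signature(cfg)
  wl <- phantom_wavelengths(cfg)
  oracle <- exp(-0.5 * ((wl - 1300) / 40)^2) +
    0.5 * exp(-0.5 * ((wl - 1700) / 60)^2)
  expect_equal(sig, oracle, tolerance = 1e-12)
  expect_true(all(sig >= 0))
  # single narrow peak at a band centre peaks at that band
  cfg1 <- phantom_config(n_bands = 50L, wavelength_start_nm = 1000,
                         wavelength_step_nm = 10,
                         analyte_peaks = data.frame(center_nm = 1200,
                                                    width_nm = 1,
                                                    amplitude = 1))
  expect_equal(which.max(make_signature(cfg1)), 21L)
  # no peaks: zero vector; off-axis peak warns
  cfg0 <- phantom_config(analyte_peaks = data.frame(center_nm = numeric(),
                                                    width_nm = numeric(),
                                                    amplitude = numeric()))
  expect_equal(make_signature(cfg0), rep(0, 256))
  cfg_out <- phantom_config(n_bands = 10L, wavelength_start_nm = 1000,
                            wavelength_step_nm = 10,
                            analyte_peaks = data.frame(center_nm = 5000,
                                                       width_nm = 10,
                                                       amplitude = 1))
  expect_warning(make_signature(cfg_out), "outside")
})

test_that("noise-free calibration spectra follow the closed-form model", {
  cfg <- test_phantom_config(noise_sd = 0, offset_sd = 0,
                             scatter_range = c(1, 1),
                             interferent_sd = 0,
                             interferent_peaks = data.frame(
                               center_nm = numeric(), width_nm = numeric(),
                               amplitude = numeric()))
  cal <- generate_calibration_set(cfg, 2, seed = 5)
  wl <- phantom_wavelengths(cfg)
  u <- (wl - min(wl)) / (max(wl) - min(wl))
  baseline <- drop(outer(u, seq_along(cfg$baseline_coef) - 1, `^`) %*%
                     cfg$baseline_coef)
  for (i in 1:2) {
    c_i <- cal$table$nitrate_mg_per_kg[i]
    A <- baseline + (c_i / cfg$c_ref_mg_kg) * make_signature(cfg)
    expect_equal(as.numeric(cal$spectra[i, ]), 10^(-A),
                 tolerance = 1e-12)
  }
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- test_phantom_config()
  expect_identical(generate_calibration_set(cfg, 10, seed = 9),
                   generate_calibration_set(cfg, 10, seed = 9))
  expect_identical(generate_leaf_phantom(cfg, 64, 64, seed = 9),
                   generate_leaf_phantom(cfg, 64, 64, seed = 9))
  expect_identical(generate_storage_series(seed = 9),
                   generate_storage_series(seed = 9))
})

test_that("a 210-sample draw respects the configured calibration range", {
  cal <- generate_calibration_set(phantom_config(), 210, seed = 17)
  s <- summarize_references(cal)
  expect_equal(s$n, 210L)
  expect_gte(s$min, 2178)
  expect_lte(s$max, 8767)
})

test_that("phantom truth encodes the tissue concentration ordering", {
  cfg <- test_phantom_config(blade_range_mg_kg = c(3000, 3000),
                             vein_range_mg_kg = c(12000, 12000),
                             petiole_range_mg_kg = c(14000, 14000))
  ph <- generate_leaf_phantom(cfg, 64, 80, seed = 2)
  lab <- ph$region_labels
  m_blade <- mean(ph$concentration_truth[lab == "blade"])
  m_vein <- mean(ph$concentration_truth[lab == "vein"])
  m_pet <- mean(ph$concentration_truth[lab == "petiole"])
  expect_gt(m_vein, m_blade)
  expect_gte(m_pet, m_vein)
  expect_true(all(c("blade", "vein", "petiole") %in% lab))
  # truth, labels and cube are congruent
  expect_equal(dim(ph$concentration_truth), dim(ph$cube$data)[1:2])
  expect_equal(is.na(ph$concentration_truth),
               !unclass(ph$mask_truth))
  expect_error(generate_leaf_phantom(cfg, 32, 80), ">= 64")
})

test_that("stripe injection is visible and switchable", {
  cfg_on <- test_phantom_config()
  cfg_off <- test_phantom_config(stripe_amplitude = 0)
  fcfg <- stripe_filter_config()
  e_on <- {
    ph <- generate_leaf_phantom(cfg_on, 64, 80, seed = 6)
    refl <- compute_reflectance(ph$cube, ph$refs)
    stripe_energy(refl$data[, , 30], fcfg)
  }
  e_off <- {
    ph <- generate_leaf_phantom(cfg_off, 64, 80, seed = 6)
    refl <- compute_reflectance(ph$cube, ph$refs)
    stripe_energy(refl$data[, , 30], fcfg)
  }
  expect_gt(e_on, 5 * e_off)
})

test_that("zero-noise phantom reflectance matches the forward model", {
  cfg <- test_phantom_config(noise_sd = 0, stripe_amplitude = 0,
                             interferent_sd = 0,
                             blade_range_mg_kg = c(4000, 4000),
                             vein_range_mg_kg = c(4000, 4000),
                             petiole_range_mg_kg = c(4000, 4000))
  ph <- generate_leaf_phantom(cfg, 64, 64, seed = 1)
  refl <- compute_reflectance(ph$cube, ph$refs)
  expected <- nitramap:::forward_reflectance(cfg, 4000)
  leaf_px <- which(unclass(ph$mask_truth), arr.ind = TRUE)[1, ]
  expect_equal(refl$data[leaf_px[1], leaf_px[2], ], expected,
               tolerance = 1e-9)
  bg_px <- which(!unclass(ph$mask_truth), arr.ind = TRUE)[1, ]
  expect_equal(refl$data[bg_px[1], bg_px[2], ],
               rep(cfg$background_reflectance, cfg$n_bands),
               tolerance = 1e-9)
})

test_that("the forward model is invertible by low-rank PLS at zero noise", {
  cfg <- test_phantom_config(noise_sd = 0, offset_sd = 0,
                             scatter_range = c(1, 1), interferent_sd = 0)
  cal <- generate_calibration_set(cfg, 40, seed = 23)
  sm <- apply_recipe(cal$spectra,
                     preprocess_recipe(step_snv(), step_derivative(1, 2)))
  y <- cal$table$nitrate_mg_per_kg
  fit <- fit_pls(sm, y, 3)
  r2 <- regression_metrics(y, predict(fit, sm))$r2
  expect_gt(r2, 0.999)
})

test_that("calibration tables round-trip through CSV", {
  cal <- generate_calibration_set(test_phantom_config(), 8, seed = 3)
  path <- file.path(tempdir(), "cal.csv")
  write_calibration_csv(cal, path)
  back <- read_calibration_csv(path)
  expect_equal(back$table$nitrate_mg_per_kg,
               cal$table$nitrate_mg_per_kg, tolerance = 1e-12)
  expect_equal(unclass(back$spectra), unclass(cal$spectra),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(wavelengths(back$spectra), wavelengths(cal$spectra))
})

test_that("storage generator honours its decay laws", {
  quiet <- generate_storage_series(rnc_decay_per_day = rep(0, 4),
                                   rwc_decay_per_day = 0,
                                   obs_noise_sd = 0, seed = 2)
  s <- storage_series(quiet)
  expect_equal(s$mean_rnc, rep(1, nrow(s)))
  expect_equal(s$mean_rwc, rep(1, nrow(s)))
  # ordered rates produce strictly ordered day-4 expectations
  noisy <- generate_storage_series(seed = 12)
  s4 <- storage_series(noisy)
  s4 <- s4[s4$day == 4, ]
  s4 <- s4[order(s4$temperature_C), ]
  expect_true(all(diff(s4$mean_rnc) < 0))
})
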