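# Shared fixtures: a small calibration model and matching phantoms.
local({
  cfg <<- test_phantom_config()
  cal <- generate_calibration_set(cfg, 60, seed = 14)
  rec <- preprocess_recipe(step_snv(), step_derivative(1, 2))
  sm <- apply_recipe(cal$spectra, rec)
  model <<- fit_pls(sm, cal$table$nitrate_mg_per_kg, 4, recipe = rec)
})

test_that("a uniform low-noise phantom is recovered within 5 percent", {
  cfg_u <- test_phantom_config(blade_range_mg_kg = c(4000, 4000),
                               vein_range_mg_kg = c(4000, 4000),
                               petiole_range_mg_kg = c(4000, 4000),
                               noise_sd = 0.001)
  ph <- generate_leaf_phantom(cfg_u, 64, 80, seed = 4)
  refl <- compute_reflectance(ph$cube, ph$refs)
  ds <- destripe_cube(refl, stripe_filter_config())
  mask <- segment_leaf(ds)
  mp <- map_concentration(ds, model, mask)
  mean_inmask <- mean(mp$values[unclass(mp$mask)])
  expect_lt(abs(mean_inmask - 4000) / 4000, 0.05)
})

test_that("tissue ordering vein > blade is preserved in the map", {
  cfg_2 <- test_phantom_config(blade_range_mg_kg = c(3000, 3000),
                               vein_range_mg_kg = c(12000, 12000),
                               petiole_range_mg_kg = c(12000, 12000))
  ph <- generate_leaf_phantom(cfg_2, 64, 80, seed = 8)
  refl <- compute_reflectance(ph$cube, ph$refs)
  ds <- destripe_cube(refl, stripe_filter_config())
  mp <- map_concentration(ds, model, ph$mask_truth)
  blade <- region_mean(mp, leaf_mask(ph$region_labels == "blade"))
  vein <- region_mean(mp, leaf_mask(ph$region_labels == "vein"))
  expect_gt(vein, blade)
  # out-of-mask pixels never receive a value
  expect_true(all(is.na(mp$values[!unclass(ph$mask_truth)])))
})

test_that("region means are additive over disjoint regions", {
  vals <- matrix(runif(30 * 40, 2000, 6000), 30, 40)
  mask <- leaf_mask(matrix(TRUE, 30, 40))
  mp <- concentration_map(vals, mask)
  top <- leaf_mask(rbind(matrix(TRUE, 15, 40), matrix(FALSE, 15, 40)))
  bot <- leaf_mask(rbind(matrix(FALSE, 15, 40), matrix(TRUE, 15, 40)))
  whole <- region_mean(mp, mask)
  expect_equal(whole, (region_mean(mp, top) * 600 +
                         region_mean(mp, bot) * 600) / 1200,
               tolerance = 1e-12)
  expect_equal(region_mean(concentration_map(matrix(7, 2, 2),
                                             leaf_mask(matrix(TRUE, 2, 2))),
                           leaf_mask(matrix(TRUE, 2, 2))), 7)
  expect_error(region_mean(mp, leaf_mask(matrix(FALSE, 30, 40))),
               "intersect")
})

test_that("mapping is independent of the prediction block size", {
  cfg_b <- test_phantom_config()
  ph <- generate_leaf_phantom(cfg_b, 64, 64, seed = 10)
  refl <- compute_reflectance(ph$cube, ph$refs)
  m1 <- map_concentration(refl, model, ph$mask_truth, block_size = 64L)
  m2 <- map_concentration(refl, model, ph$mask_truth, block_size = 8192L)
  expect_identical(m1$values, m2$values)
  # identical inputs give bit-identical maps
  m3 <- map_concentration(refl, model, ph$mask_truth, block_size = 64L)
  expect_identical(m1$values, m3$values)
})

test_that("clipping is applied and counted", {
  vals <- matrix(c(20000, 5000, 3000, -50), 2, 2)
  mask <- leaf_mask(matrix(TRUE, 2, 2))
  mp <- concentration_map(vals, mask, clip_bounds = c(0, 15000))
  expect_equal(mp$n_clipped, 2)
  expect_equal(max(mp$values), 15000)
  expect_equal(min(mp$values), 0)
})

test_that("predicting a region mean equals the mean pixel prediction", {
  # spectrally homogeneous region, zero noise: preprocessing is
  # row-independent, so mean-then-predict == predict-then-mean
  cfg_h <- test_phantom_config(blade_range_mg_kg = c(5000, 5000),
                               vein_range_mg_kg = c(5000, 5000),
                               petiole_range_mg_kg = c(5000, 5000),
                               noise_sd = 0, stripe_amplitude = 0,
                               interferent_sd = 0)
  ph <- generate_leaf_phantom(cfg_h, 64, 64, seed = 3)
  refl <- compute_reflectance(ph$cube, ph$refs)
  # vein pixels all share one concentration, hence one spectrum
  vein <- leaf_mask(ph$region_labels == "vein")
  mp <- map_concentration(refl, model, vein)
  mu <- mean_spectrum(refl, vein)
  pred_of_mean <- predict(model, apply_recipe(mu, model$recipe))
  expect_equal(region_mean(mp, vein), unname(pred_of_mean),
               tolerance = 1e-6)
})

test_that("map smoothing preserves interior region means", {
  set.seed(12)
  vals <- matrix(3000 + rnorm(40 * 50, 0, 200), 40, 50)
  mask <- leaf_mask(matrix(TRUE, 40, 50))
  mp <- concentration_map(vals, mask)
  sm <- smooth_map(mp, 5L)
  interior <- matrix(FALSE, 40, 50); interior[10:30, 10:40] <- TRUE
  ri <- leaf_mask(interior)
  expect_lt(abs(region_mean(sm, ri) - region_mean(mp, ri)) /
              region_mean(mp, ri), 0.005)
})

test_that("rendering exports lossless numbers beside the image", {
  vals <- matrix(c(3000.123456789, 4000.987654321, NA, 5000.5), 2, 2)
  mask <- leaf_mask(matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2))
  mp <- concentration_map(vals, mask)
  p_png <- file.path(tempdir(), "map.png")
  out <- render_map(mp, p_png)
  back <- read_map_csv(out$csv)
  expect_identical(back, mp$values)
  img <- png::readPNG(p_png)
  # background pixel rendered neutral grey, leaf pixels coloured
  expect_equal(img[1, 2, ], c(0.5, 0.5, 0.5), tolerance = 0.01)
  # constant map renders a single colour inside the leaf
  cm <- concentration_map(matrix(4000, 2, 2), leaf_mask(matrix(TRUE, 2, 2)))
  render_map(cm, p_png)
  img2 <- png::readPNG(p_png)
  expect_equal(img2[1, 1, ], img2[2, 2, ])
})
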