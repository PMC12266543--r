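test_that("OCT generator renders the requested thickness and records exact truth", {
  empty <- gen_oct_volume(c(16, 16, 32), mean_thickness = 0,
                          noise_model = "none", seed = 1)
  expect_equal(empty$truth$mean_thickness, 0)
  expect_true(all(empty$volume$intensities == 10))

  sim <- gen_oct_volume(c(32, 32, 64), mean_thickness = 20,
                        noise_model = "none", seed = 1)
  expect_lt(abs(sim$truth$mean_thickness - 20), 1.45)
  # truth mean is the mean of the quantized height field by construction
  expect_equal(sim$truth$mean_thickness, mean(sim$truth$height_field))
  expect_true(all(sim$truth$height_field >= 0))
  # rendered foreground voxel count matches the quantized field
  nvox <- round(sim$truth$height_field / 1.45)
  expect_equal(sum(sim$volume$intensities == 100), sum(nvox))

  expect_error(gen_oct_volume(c(8, 8, 16), mean_thickness = 1000, seed = 1),
               class = "biofilmq_sizing_error")
})

test_that("OCT generator is seed-deterministic with seed-dependent fields", {
  a <- gen_oct_volume(c(16, 16, 32), mean_thickness = 15, seed = 1)
  b <- gen_oct_volume(c(16, 16, 32), mean_thickness = 15, seed = 1)
  c <- gen_oct_volume(c(16, 16, 32), mean_thickness = 15, seed = 2)
  expect_identical(a$volume$intensities, b$volume$intensities)
  expect_false(identical(a$truth$height_field, c$truth$height_field))
  # same construction target: summary statistics agree across seeds
  expect_lt(abs(a$truth$mean_thickness - c$truth$mean_thickness), 2 * 1.45)
})

test_that("CLSM generator ground truth obeys the Cavalieri identity", {
  empty <- gen_clsm_stack(c(64, 64), object_density = 0, seed = 1)
  expect_equal(empty$truth$true_biovolume, 0)
  expect_true(all(empty$truth$slice_areas == 0))

  sim <- gen_clsm_stack(c(128, 128), n_slices = 3, object_density = 0.05,
                        pixel_size = 0.5, slice_spacing = 2, seed = 4)
  expect_equal(sim$truth$true_biovolume,
               sum(sim$truth$slice_areas) * sim$truth$slice_spacing)
  # per-slice area equals rendered pixel count times pixel area
  counts <- vapply(sim$truth$object_masks, sum, numeric(1))
  expect_equal(sim$truth$slice_areas, counts * 0.5^2)

  a <- gen_clsm_stack(c(64, 64), object_density = 0.05, seed = 9)
  b <- gen_clsm_stack(c(64, 64), object_density = 0.05, seed = 9)
  expect_identical(a$stack$slices, b$stack$slices)

  expect_error(gen_clsm_stack(c(0, 64), seed = 1),
               class = "biofilmq_validation_error")
})

test_that("single rendered disk gives biovolume = pixel count x area x spacing", {
  sim <- gen_clsm_stack(c(64, 64), n_slices = 1, object_density = 1 / (64 * 64),
                        object_radius_px = 10, pixel_size = 1,
                        slice_spacing = 2, seed = 8)
  count <- sum(sim$truth$object_masks[[1]])
  expect_gt(count, 0)
  expect_equal(sim$truth$true_biovolume, count * 1 * 2)
})

test_that("ratiometric generator follows the forward calibration model", {
  params <- default_calib_params()
  sim <- gen_ratiometric_pair(c(32, 32), true_ph = 5.5, cell_density = 0,
                              noise_sd = 0, seed = 1)
  expect_equal(unique(as.vector(sim$pair$green / sim$pair$red)),
               calib_curve(5.5, params))

  edge <- gen_ratiometric_pair(c(16, 16), true_ph = 7.8, cell_density = 0,
                               noise_sd = 0, seed = 1)
  expect_equal(unique(as.vector(edge$pair$green / edge$pair$red)),
               calib_curve(7.8, params))

  field <- matrix(rep(c(5, 6), each = 16 * 8), 16, 16)
  two <- gen_ratiometric_pair(c(16, 16), true_ph = field, cell_density = 0,
                              noise_sd = 0, seed = 1)
  ratios <- sort(unique(as.vector(two$pair$green / two$pair$red)))
  expect_equal(ratios, sort(calib_curve(c(5, 6), params)))

  expect_error(gen_ratiometric_pair(c(8, 8), true_ph = 8.5, seed = 1),
               class = "biofilmq_range_error")
})

test_that("calibration table generator matches the protocol's buffer series", {
  tab <- gen_calibration_table(noise_sd = 0, seed = 1)
  expect_equal(nrow(tab), 20L)
  expect_equal(tab$pH, seq(4.0, 7.8, by = 0.2))
  expect_equal(tab$ratio, calib_curve(tab$pH, default_calib_params()))

  # pooled residual SD across seeds reflects the requested noise level
  resid <- unlist(lapply(1:20, function(s) {
    t2 <- gen_calibration_table(noise_sd = 0.01, seed = s)
    t2$ratio - calib_curve(t2$pH, default_calib_params())
  }))
  expect_gt(sd(resid), 0.008)
  expect_lt(sd(resid), 0.012)
  expect_identical(gen_calibration_table(noise_sd = 0.01, seed = 3),
                   gen_calibration_table(noise_sd = 0.01, seed = 3))
})

test_that("trial generator plants outliers and encodes the effect ratio", {
  clean <- gen_trial_dataset(n_outliers = 0, seed = 1)
  expect_length(clean$truth$outlier_indices, 0)
  expect_true(all(clean$table$outcome > 0))
  expect_equal(nrow(clean$table), 11 * 6 * 2)

  dirty <- gen_trial_dataset(n_outliers = 3, seed = 2)
  idx <- dirty$truth$outlier_indices
  expect_length(idx, 3)
  expect_true(all(dirty$table$outcome[idx] >=
                    10 * mean(dirty$table$outcome[-idx])))

  # null effect: arm means agree at large n
  big <- gen_trial_dataset(n_participants = 200, n_per_arm = 10,
                           effect_ratio = 1, seed = 3)
  means <- tapply(big$table$outcome, big$table$treatment, mean)
  expect_lt(abs(means[["enzyme"]] / means[["control"]] - 1), 0.05)

  expect_error(gen_trial_dataset(effect_ratio = -1, seed = 1),
               class = "biofilmq_validation_error")
})
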