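test_that("noiseless calibration fit recovers the generating curve", {
  tab <- gen_calibration_table(noise_sd = 0, seed = 1)
  model <- fit_calibration(tab)
  grid <- seq(4, 7.8, length.out = 500)
  expect_lt(max(abs(calib_curve(grid, model$params) -
                      calib_curve(grid, default_calib_params()))), 1e-6)
  expect_lt(model$fit_rmse, 1e-8)
  expect_equal(model$domain, c(4, 7.8))
})

test_that("degenerate calibration tables are rejected", {
  flat <- data.frame(pH = seq(4, 7.8, 0.2), ratio = rep(0.5, 20))
  expect_error(fit_calibration(flat), class = "biofilmq_fit_error")
  short <- data.frame(pH = c(4, 4.2, 4.4), ratio = c(1.1, 1.0, 0.9))
  expect_error(fit_calibration(short), class = "biofilmq_validation_error")
})

test_that("ratio-to-pH inversion round-trips and clamps at the domain", {
  model <- fit_calibration(gen_calibration_table(noise_sd = 0, seed = 1))
  withr::with_seed(61, {
    ph <- runif(100, 4, 7.8)
  })
  expect_lt(max(abs(ratio_to_ph(calib_curve(ph, model$params), model) - ph)),
            1e-9)
  # domain edges
  expect_equal(ratio_to_ph(model$ratio_range[1], model), 4)
  expect_equal(ratio_to_ph(model$ratio_range[2], model), 7.8)
  # clamping policy
  expect_equal(ratio_to_ph(model$ratio_range[1] * 1.5, model, clamp = TRUE), 4)
  expect_error(ratio_to_ph(model$ratio_range[1] * 1.5, model, clamp = FALSE),
               class = "biofilmq_range_error")
  expect_error(ratio_to_ph(-0.1, model), class = "biofilmq_validation_error")
  # strict monotonicity of the inverse in the ratio
  rr <- seq(model$ratio_range[2] + 1e-6, model$ratio_range[1] - 1e-6,
            length.out = 200)
  expect_true(all(diff(ratio_to_ph(rr, model)) < 0))
})

test_that("extracellular segmentation excludes cells and keeps dye signal", {
  # uniform dye, no cells: every pixel is extracellular
  sim <- gen_ratiometric_pair(c(32, 32), true_ph = 6, cell_density = 0,
                              noise_sd = 0, seed = 1)
  mask <- segment_extracellular(sim$pair)
  expect_true(all(mask))

  # rendered cells are excluded exactly; dye coverage is complete
  simc <- gen_ratiometric_pair(c(64, 64), true_ph = 6, cell_density = 6,
                               noise_sd = 0, seed = 3)
  m <- segment_extracellular(simc$pair)
  expect_gt(sum(simc$truth$cell_mask), 0)
  expect_equal(sum(m & simc$truth$cell_mask), 0)
  expect_gte(mean(m[!simc$truth$cell_mask]), 0.95)

  # all-dark pair: nothing above the floor
  dark <- new_ratio_image_pair(matrix(0, 8, 8), matrix(0, 8, 8))
  expect_error(segment_extracellular(dark),
               class = "biofilmq_no_signal_error")
})

test_that("mean extracellular pH recovers uniform and mixed truth", {
  model <- fit_calibration(gen_calibration_table(noise_sd = 0, seed = 1))
  sim <- gen_ratiometric_pair(c(32, 32), true_ph = 5.5, cell_density = 0,
                              noise_sd = 0, seed = 1)
  res <- mean_extracellular_ph(sim$pair, model)
  expect_lt(abs(res$mean_ph - 5.5), 1e-6)
  expect_equal(res$n_pixels_used, 32 * 32)
  expect_equal(res$excluded_cell_fraction, 0)

  # half 5.0 / half 6.0: per-pixel averaging gives exactly 5.5
  field <- matrix(rep(c(5, 6), each = 32 * 16), 32, 32)
  two <- gen_ratiometric_pair(c(32, 32), true_ph = field, cell_density = 0,
                              noise_sd = 0, seed = 1)
  res2 <- mean_extracellular_ph(two$pair, model)
  expect_lt(abs(res2$mean_ph - 5.5), 1e-6)

  # mean-ratio averaging converts the mean ratio once and differs
  res3 <- mean_extracellular_ph(two$pair, model, avg = "mean-ratio")
  expected3 <- ratio_to_ph(mean(calib_curve(c(5, 6),
                                            default_calib_params())), model)
  expect_lt(abs(res3$mean_ph - expected3), 1e-6)
  expect_false(isTRUE(all.equal(res3$mean_ph, res2$mean_ph)))
})

test_that("calibration model serialization round-trips", {
  model <- fit_calibration(gen_calibration_table(noise_sd = 0.01, seed = 5))
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration_model(model, path)
  back <- read_calibration_model(path)
  expect_equal(back$params, model$params)
  expect_equal(back$domain, model$domain)
  grid <- seq(4, 7.8, length.out = 50)
  expect_equal(ratio_to_ph(calib_curve(grid, back$params), back),
               ratio_to_ph(calib_curve(grid, model$params), model))
})
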