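test_that("transition constructor enforces mass and energy constraints", {
  expect_error(mrm_transition("PMB1", 100, 602, 30, 2.8), "precursor")
  expect_error(mrm_transition("PMB1", 602.25, 100.8, -5, 2.8), "collision")
  tr <- default_transitions()
  expect_named(tr, c("PMB1", "PMB2", "PME1", "PME2"))
  expect_equal(tr$PMB1$precursor_mz, 602.25)
  expect_equal(tr$PMB1$product_mz, 100.80)
  expect_equal(tr$PMB2$precursor_mz, 595.40)
  expect_equal(tr$PME1$precursor_mz, 585.85)
  expect_equal(tr$PME2$precursor_mz, 578.95)
  expect_true(all(vapply(tr, function(t) t$collision_energy == 30, logical(1))))
})

test_that("signal model validates component fractions and noise", {
  expect_error(signal_model(subtype_fraction = c(PMB1 = 0.8, PMB2 = 0.3)),
               "sum to 1")
  expect_error(signal_model(response_factor = 0), "response_factor")
  expect_error(signal_model(baseline_noise_sd = -1), "baseline_noise_sd")
  expect_error(signal_model(matrix_suppression = 1.2), "matrix_suppression")
})

test_that("simulated chromatogram integrates to the model-implied area", {
  m <- clean_model()
  tr <- default_transitions()$PMB1
  w <- peak_window(tr, m)

  # zero analyte: flat baseline, zero area
  ch0 <- simulate_chromatogram(tr, 0, m)
  expect_true(all(ch0$intensity == 0))
  expect_equal(integrate_peak(ch0, w)$area, 0)

  # closed-form Gaussian area oracle: amount * fraction * rf * suppression
  ch <- simulate_chromatogram(tr, 100, m)
  area <- integrate_peak(ch, w)$area
  expect_lt(abs(area / 1e5 - 1), 1e-3)

  # linearity: doubling the amount doubles the area
  ch2 <- simulate_chromatogram(tr, 200, m)
  expect_equal(integrate_peak(ch2, w)$area, 2 * area, tolerance = 1e-9)
})

test_that("chromatogram noise is reproducible under a fixed seed", {
  m <- signal_model(baseline_noise_sd = 10, seed = 7L)
  tr <- default_transitions()$PMB1
  a <- simulate_chromatogram(tr, 50, m)
  b <- simulate_chromatogram(tr, 50, m)
  expect_identical(a$intensity, b$intensity)
  c_ <- simulate_chromatogram(tr, 50, m, seed = 8L)
  expect_false(identical(a$intensity, c_$intensity))
})

test_that("chromatogram simulation rejects invalid acquisition settings", {
  m <- clean_model()
  tr <- default_transitions()$PMB1
  expect_error(simulate_chromatogram(tr, 10, m, sampling_rate = 0),
               "invalid parameter")
  expect_error(simulate_chromatogram(tr, 10, m, duration = -1),
               "invalid parameter")
  expect_error(simulate_chromatogram(tr, -5, m), "amount")
  expect_error(simulate_chromatogram(tr, 10, m, duration = 2.9),
               "5 peak widths")
})

test_that("calibration series uses the seven standard levels by default", {
  tbl <- simulate_calibration_series(model = noiseless_model(), noise_cv = 0)
  expect_setequal(unique(tbl$level), c(10, 20, 40, 100, 200, 500, 1000))
  expect_equal(nrow(tbl), 7 * 3 * 2)  # levels x replicates x subtypes
  # noiseless: areas exactly proportional to level within each subtype
  for (s in c("PMB1", "PMB2")) {
    sub <- tbl[tbl$subtype == s, ]
    expect_equal(sub$area / sub$level,
                 rep((sub$area / sub$level)[1], nrow(sub)))
  }
  expect_error(simulate_calibration_series(levels = numeric(0)), "non-empty")
  expect_error(simulate_calibration_series(levels = c(10, 10, 40)),
               "strictly")
  expect_error(simulate_calibration_series(levels = c(-1, 10)), "positive")
})

test_that("calibration noise reproduces the injected coefficient of variation", {
  tbl <- simulate_calibration_series(levels = 100, model = noiseless_model(),
                                     replicates_per_level = 1000,
                                     noise_cv = 3, seed = 11L)
  a <- tbl$area[tbl$subtype == "PMB1"]
  expect_lt(abs(100 * sd(a) / mean(a) - 3), 0.3)
})

test_that("validation experiment table supports all downstream figures of merit", {
  tbl <- simulate_validation_experiment(seed = 3L)
  expect_setequal(unique(tbl$nominal), c(10, 50, 200))
  expect_setequal(unique(tbl$design_arm),
                  c("pre_spike", "post_spike", "solvent"))
  expect_true(all(is.na(tbl$measured[tbl$design_arm != "pre_spike"])))
  expect_true(all(!is.na(tbl$measured[tbl$design_arm == "pre_spike"])))

  # noiseless, lossless: measured equals nominal everywhere
  exact <- simulate_validation_experiment(intra_cv = 0, inter_cv = 0,
                                          recovery_mean = 100, me_mean = 100)
  pre <- exact[exact$design_arm == "pre_spike", ]
  expect_equal(pre$measured, pre$nominal)

  expect_error(simulate_validation_experiment(intra_cv = -1),
               "CVs must be >= 0")
  expect_error(simulate_validation_experiment(intra_cv = 5, inter_cv = 2),
               "pooled")
  expect_error(simulate_validation_experiment(n_intra = 1), "n_intra")
})

test_that("soil series follows the production-decay curve with a day-14 peak", {
  models <- default_dynamics_models(replicate_cv = 0)
  ts <- simulate_soil_timeseries(models = models)
  expect_s3_class(ts, "soil_timeseries")
  expect_equal(nrow(ts), 6 * 5 * 3)

  means <- aggregate(concentration ~ dose_group + day, data = ts, FUN = mean)
  # control flat at background
  ctrl <- means[means$dose_group == 0, ]
  expect_equal(ctrl$concentration, rep(0.0235, 5))
  # the two highest doses peak at day 14 of the sampling grid
  for (d in c(1e8, 2e8)) {
    g <- means[means$dose_group == d, ]
    expect_equal(g$day[which.max(g$concentration)], 14)
  }
  # amplitude monotone in dose: noiseless trajectories ordered pointwise
  for (day in c(7, 14, 21, 28)) {
    byd <- means[means$day == day, ]
    byd <- byd[order(byd$dose_group), ]
    expect_false(is.unsorted(byd$concentration))
  }
})

test_that("soil series generation is deterministic under a fixed seed", {
  a <- simulate_soil_timeseries(seed = 5L)
  b <- simulate_soil_timeseries(seed = 5L)
  expect_identical(a, b)
  c_ <- simulate_soil_timeseries(seed = 6L)
  expect_false(identical(a$concentration, c_$concentration))
})

test_that("dynamics model rejects a rise slower than the decline", {
  expect_error(dynamics_model(1e8, 0.5, production_rate = 0.05,
                              decay_rate = 0.1), "exceed")
  expect_error(dynamics_model(-1, 0.5), "dose_cfu")
})
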