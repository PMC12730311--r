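test_that("selectivity ratio and its inclusive 5% bound", {
  expect_equal(assess_selectivity(0, 1e5)$ratio, 0)
  expect_true(assess_selectivity(0, 1e5)$pass)
  # boundary inclusive: exactly 5% still passes
  at5 <- assess_selectivity(5000, 1e5)
  expect_equal(at5$ratio, 5)
  expect_true(at5$pass)
  over <- assess_selectivity(8000, 1e5)
  expect_equal(over$ratio, 8)
  expect_false(over$pass)
  expect_error(assess_selectivity(10, 0), "invalid reference")
})

test_that("accuracy is the mean recovery of nominal, in percent", {
  expect_equal(compute_accuracy(c(10, 10, 10), 10), 100)
  expect_equal(compute_accuracy(c(96, 97, 97), 100), 96.66667,
               tolerance = 1e-6)
  expect_error(compute_accuracy(c(1, 2), 0), "nominal")
})

test_that("precision is the sample relative standard deviation", {
  expect_equal(compute_precision(c(5, 5, 5, 5)), 0)
  expect_equal(compute_precision(c(98, 100, 102)), 2)
  expect_error(compute_precision(7), "2 replicates")
  expect_error(compute_precision(c(-1, 1)), "undefined RSD")
})

test_that("recovery and matrix effect are direct response ratios", {
  expect_equal(compute_recovery(1000, 1000), 100)
  expect_equal(compute_recovery(861.2, 1000), 86.12)
  expect_error(compute_recovery(1, 0), "invalid reference")
  expect_equal(compute_matrix_effect(1000, 1000), 100)
  expect_equal(compute_matrix_effect(902, 1000), 90.2)
  expect_error(compute_matrix_effect(1, -1), "invalid reference")
})

test_that("ratio statistics are scale invariant", {
  for (k in c(0.01, 1, 250)) {
    expect_equal(compute_recovery(861.2 * k, 1000 * k), 86.12)
    expect_equal(compute_matrix_effect(902 * k, 1000 * k), 90.2)
    expect_equal(compute_precision(c(98, 100, 102) * k), 2)
    expect_equal(assess_selectivity(5000 * k, 1e5 * k)$ratio, 5)
  }
})

test_that("the generator's matrix suppression passes through to the ME estimate", {
  m <- signal_model(matrix_suppression = 0.877, baseline_noise_sd = 0)
  tbl <- simulate_validation_experiment(model = m, intra_cv = 0, inter_cv = 0,
                                        me_mean = 87.7)
  rep <- validation_report(tbl)
  expect_equal(rep$me_mean, rep(87.7, 3), tolerance = 1e-9)
})

test_that("estimated figures of merit converge to the injected parameters", {
  tbl <- simulate_validation_experiment(spike_levels = 50,
                                        n_intra = 40, n_days = 60,
                                        intra_cv = 3, inter_cv = 4,
                                        recovery_mean = 86, me_mean = 89,
                                        seed = 21L)
  rep <- validation_report(tbl)
  expect_lt(abs(rep$rsd_inter - 4), 0.4)
  expect_lt(abs(rep$recovery_mean - 86), 1)
  expect_lt(abs(rep$me_mean - 89), 1)
  expect_lt(abs(rep$accuracy_inter - 100), 1)
  # intra-day RSD from a wide single day
  intra <- simulate_validation_experiment(spike_levels = 50,
                                          n_intra = 10000, n_days = 2,
                                          intra_cv = 3, inter_cv = 3,
                                          seed = 22L)
  rep2 <- validation_report(intra)
  expect_lt(abs(rep2$rsd_intra - 3), 0.3)
})

test_that("the published validation panel passes every criterion", {
  ev <- evaluate_method(published_validation_report())
  expect_true(ev$pass)
  expect_true(all(ev$verdicts$pass))
  # one row per level per metric
  expect_equal(nrow(ev$verdicts), 3 * 6)
})

test_that("window boundaries follow their stated semantics", {
  rep <- published_validation_report()
  # accuracy window inclusive: 85 passes, 84.9 fails
  rep$accuracy_intra[1] <- 85
  expect_true(evaluate_method(rep)$pass)
  rep$accuracy_intra[1] <- 84.9
  ev <- evaluate_method(rep)
  expect_false(ev$pass)
  expect_false(ev$verdicts$pass[ev$verdicts$metric == "accuracy_intra" &
                                  ev$verdicts$nominal == 10])
  # RSD bound strict: exactly 15 fails
  rep <- published_validation_report()
  rep$rsd_inter[2] <- 15
  expect_false(evaluate_method(rep)$pass)
  rep$rsd_inter[2] <- 14.99
  expect_true(evaluate_method(rep)$pass)
  # recovery inclusive at 80 and 120
  rep <- published_validation_report()
  rep$recovery_mean[3] <- 80
  expect_true(evaluate_method(rep)$pass)
  rep$recovery_mean[3] <- 120
  expect_true(evaluate_method(rep)$pass)
  rep$recovery_mean[3] <- 120.01
  expect_false(evaluate_method(rep)$pass)
})

test_that("worsening any single figure never flips a fail to a pass", {
  base <- published_validation_report()
  worsen <- list(
    accuracy_intra = function(r) { r$accuracy_intra[1] <- 84; r },
    rsd_intra      = function(r) { r$rsd_intra[1] <- 16; r },
    accuracy_inter = function(r) { r$accuracy_inter[2] <- 120; r },
    rsd_inter      = function(r) { r$rsd_inter[2] <- 20; r },
    recovery_mean  = function(r) { r$recovery_mean[3] <- 75; r },
    me_mean        = function(r) { r$me_mean[3] <- 80; r }
  )
  for (f in worsen) {
    expect_false(evaluate_method(f(base))$pass)
  }
  expect_error(evaluate_method(base[, -2]), "incomplete report")
})
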