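test_that("summary finds peak, peak day, and percent decline", {
  # constant trajectory: no decline, peak at first day
  flat <- soil_timeseries(data.frame(
    dose_group = 0, day = rep(c(0, 7, 14), each = 2),
    replicate = rep(1:2, 3), concentration = 0.02))
  s <- summarize_timeseries(flat)
  expect_equal(s$by_dose$percent_decline, 0)
  expect_equal(s$by_dose$peak_day, 0)

  # the reported top-dose means: peak 0.221 at day 14, decline from
  # concentrations is ~29.9% (not the printed decline percentage, which
  # is inconsistent with the printed concentrations)
  top <- soil_timeseries(data.frame(
    dose_group = 2e8, day = rep(c(0, 7, 14, 21, 28)),
    replicate = 1,
    concentration = c(0.024, 0.186, 0.221, 0.19, 0.155)))
  s2 <- summarize_timeseries(top)
  expect_equal(s2$by_dose$peak_concentration, 0.221)
  expect_equal(s2$by_dose$peak_day, 14)
  expect_equal(s2$by_dose$percent_decline, 100 * (0.221 - 0.155) / 0.221,
               tolerance = 1e-9)
  expect_equal(round(s2$by_dose$percent_decline, 2), 29.86)

  # ties break toward the earliest day
  tie <- soil_timeseries(data.frame(
    dose_group = 1, day = c(0, 7, 14), replicate = 1,
    concentration = c(0.1, 0.2, 0.2)))
  expect_equal(summarize_timeseries(tie)$by_dose$peak_day, 7)
  expect_error(summarize_timeseries(flat[0, ]), "missing data")
})

test_that("day-versus-baseline ANOVA matches a sum-of-squares oracle", {
  for (s in 1:20) {
    dat <- withr::with_seed(s, data.frame(
      dose_group = 1,
      day = rep(c(0, 14), each = 4),
      replicate = rep(1:4, 2),
      concentration = abs(rnorm(8, mean = 0.1, sd = 0.03))))
    got <- compare_to_baseline(soil_timeseries(dat), 1)
    want <- anova_oracle(dat$concentration, dat$day)
    expect_close(got$f_statistic, want$f)
    expect_close(got$p_value, want$p)
  }
})

test_that("ANOVA flags separated and degenerate groups sensibly", {
  jitter <- c(-0.01, 0, 0.01)
  sep <- soil_timeseries(data.frame(
    dose_group = 1, day = rep(c(0, 7), each = 3), replicate = rep(1:3, 2),
    concentration = c(10 + jitter, 20 + jitter)))
  res <- compare_to_baseline(sep, 1)
  expect_lt(res$p_value, 0.05)
  expect_true(res$significant)

  # identical groups with zero spread: degenerate, p = 1 by convention
  const <- soil_timeseries(data.frame(
    dose_group = 1, day = rep(c(0, 7), each = 3), replicate = rep(1:3, 2),
    concentration = rep(0.1, 6)))
  res2 <- compare_to_baseline(const, 1)
  expect_equal(res2$p_value, 1)
  expect_true(res2$degenerate)
  expect_false(res2$significant)
})

test_that("null-distribution p-values are approximately uniform", {
  ps <- vapply(1:1000, function(s) {
    dat <- withr::with_seed(1000 + s, data.frame(
      dose_group = 1, day = rep(c(0, 7), each = 3), replicate = rep(1:3, 2),
      concentration = abs(rnorm(6, 1, 0.1))))
    compare_to_baseline(soil_timeseries(dat), 1)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.025)
})

test_that("first-order fit recovers exact exponential decay", {
  d <- c(0, 3, 7, 10, 14, 21, 28)
  fit <- fit_first_order(10 * exp(-0.315 * d), d)
  expect_equal(fit$k, 0.315, tolerance = 1e-9)
  expect_equal(fit$dt50, log(2) / 0.315, tolerance = 1e-9)
  expect_equal(fit$elimination_time, 5 * fit$dt50)
  expect_equal(fit$r_squared, 1)
  expect_false(fit$no_dissipation)
  # DT50 * k = ln 2 identity for random rates
  for (k in c(0.05, 0.2, 1.3)) {
    f <- fit_first_order(3 * exp(-k * d), d)
    expect_equal(f$dt50 * f$k, log(2), tolerance = 1e-9)
  }
})

test_that("constant or growing series are flagged as non-dissipating", {
  f <- fit_first_order(rep(5, 4), c(0, 7, 14, 21))
  expect_equal(f$k, 0)
  expect_true(f$no_dissipation)
  expect_identical(f$dt50, Inf)
  expect_identical(f$elimination_time, Inf)
  expect_error(fit_first_order(c(1, 0, 1), c(0, 1, 2)), "log-domain")
  expect_error(fit_first_order(c(1, 2), c(0, 1)), "3 time points")
})

test_that("post-peak dissipation fit approaches the injected decay rate", {
  # near-instant production: post-peak curve is pure exponential decay
  m <- dynamics_model(dose_cfu = 2e8, production_amplitude = 0.2,
                      background_level = 0, production_rate = 50,
                      decay_rate = 0.05, replicate_cv = 0)
  ts <- simulate_soil_timeseries(doses = 2e8, days = c(0, 1, 7, 14, 21, 28),
                                 models = list(m), n_reps = 1)
  fit <- fit_dissipation(ts, 2e8)
  expect_equal(fit$k, 0.05, tolerance = 1e-4)
  # noisy replicates: slope still converges to k_d (log-normal noise has
  # a constant log-mean offset)
  m2 <- dynamics_model(dose_cfu = 2e8, production_amplitude = 0.2,
                       background_level = 0, production_rate = 50,
                       decay_rate = 0.05, replicate_cv = 5)
  ts2 <- simulate_soil_timeseries(doses = 2e8, days = c(0, 1, 7, 14, 21, 28),
                                  models = list(m2), n_reps = 200, seed = 9L)
  fit2 <- fit_dissipation(ts2, 2e8)
  expect_lt(abs(fit2$k / 0.05 - 1), 0.05)
})
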