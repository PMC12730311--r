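# Shared fixtures for the test suite.  Everything is built in code; no
# stored data files.

# A clean single-component signal model: no noise, no suppression, unit
# bookkeeping easy to verify by hand.
clean_model <- function(response_factor = 1000, sigma = 0.05) {
  signal_model(response_factor = response_factor,
               subtype_fraction = c(PMB1 = 1, PMB2 = 0),
               peak_width_sigma = sigma,
               baseline_level = 0, baseline_noise_sd = 0,
               matrix_suppression = 1)
}

# Default two-component model without baseline noise (areas still exact).
noiseless_model <- function() signal_model(baseline_noise_sd = 0)

# Integration window: +/- 4.5 peak widths keeps truncation and baseline
# anchoring error well below 0.1% of the closed-form Gaussian area.
peak_window <- function(transition, model, k = 4.5) {
  transition$retention_time + c(-1, 1) * k * model$peak_width_sigma
}

# Equality to 1e-9 on the scale of the compared value (absolute near
# zero), for implementation-vs-oracle comparisons.
expect_close <- function(got, want, tol = 1e-9) {
  expect_lt(abs(got - want), tol * max(1, abs(want)))
}

# Independent ordinary-least-squares oracle: closed-form normal
# equations, no lm().
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- (sy - slope * sx) / n
  res <- y - intercept - slope * x
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# Independent one-way ANOVA oracle: explicit sum-of-squares
# decomposition for two or more groups.
anova_oracle <- function(values, groups) {
  groups <- as.factor(groups)
  grand <- mean(values)
  ss_between <- sum(tapply(values, groups, function(v)
    length(v) * (mean(v) - grand)^2))
  ss_within <- sum(unlist(tapply(values, groups, function(v)
    (v - mean(v))^2)))
  df_b <- nlevels(groups) - 1
  df_w <- length(values) - nlevels(groups)
  f <- (ss_between / df_b) / (ss_within / df_w)
  list(f = f, p = stats::pf(f, df_b, df_w, lower.tail = FALSE))
}

# Calibration curve matching the published soil line.
published_curve <- function() {
  calibration_curve(slope = 37777, intercept = -647896, r_squared = 0.9990)
}

# The published validation panel as a report data frame (accuracy and
# RSD in percent; recovery and matrix effect as mean +/- SD).
published_validation_report <- function() {
  data.frame(
    nominal = c(10, 50, 200),
    accuracy_intra = c(96.54, 98.47, 104.47),
    rsd_intra = c(1.88, 3.15, 2.77),
    accuracy_inter = c(99.03, 97.09, 100.28),
    rsd_inter = c(3.33, 2.63, 3.84),
    recovery_mean = c(86.12, 83.58, 88.83),
    recovery_sd = c(1.61, 3.07, 1.48),
    me_mean = c(90.2, 89.9, 87.7),
    me_sd = c(2.59, 1.42, 2.38)
  )
}
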