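#' Summarize a soil concentration time series
#'
#' Per dose group: the mean +/- SD trajectory over sampling days, the
#' peak of the mean trajectory (ties broken toward the earliest day),
#' and the percent decline from the peak to the final sampled day,
#' `100 * (peak - final) / peak`.
#'
#' @param series a [soil_timeseries()] data frame.
#' @return list with `by_day` (data frame: `dose_group`, `day`, `mean`,
#'   `sd`, `n`) and `by_dose` (data frame: `dose_group`,
#'   `peak_concentration`, `peak_day`, `final_concentration`,
#'   `percent_decline`).
#' @export
summarize_timeseries <- function(series) {
  if (nrow(series) == 0) {
    stop("missing data: empty time series", call. = FALSE)
  }
  agg <- aggregate(concentration ~ dose_group + day, data = series,
                   FUN = function(x) c(mean = mean(x),
                                       sd = if (length(x) > 1) sd(x) else 0,
                                       n = length(x)))
  by_day <- data.frame(dose_group = agg$dose_group, day = agg$day,
                       mean = agg$concentration[, "mean"],
                       sd = agg$concentration[, "sd"],
                       n = agg$concentration[, "n"])
  by_day <- by_day[order(by_day$dose_group, by_day$day), ]
  rownames(by_day) <- NULL
  by_dose <- do.call(rbind, lapply(split(by_day, by_day$dose_group), function(g) {
    peak_i <- which.max(g$mean)  # which.max takes the first maximum: earliest day
    final <- g$mean[which.max(g$day)]
    peak <- g$mean[peak_i]
    data.frame(dose_group = g$dose_group[1],
               peak_concentration = peak,
               peak_day = g$day[peak_i],
               final_concentration = final,
               percent_decline = if (peak > 0) 100 * (peak - final) / peak else 0)
  }))
  rownames(by_dose) <- NULL
  list(by_day = by_day, by_dose = by_dose[order(by_dose$dose_group), ])
}

#' Compare each sampling day to day 0 within a dose group
#'
#' Classical one-way analysis of variance of the replicate
#' concentrations of each later day against those of the first sampled
#' day, with significance declared at p < 0.05.  When both groups have
#' zero within-group variance and equal means the comparison is
#' degenerate; by convention p = 1 is returned and the row is flagged.
#'
#' @param series a [soil_timeseries()] data frame.
#' @param dose_group dose group to test.
#' @param baseline_day reference day; defaults to the earliest sampled
#'   day of the group.
#' @param alpha significance level.
#' @return data frame with one row per non-baseline day: `day`,
#'   `f_statistic`, `p_value`, `significant`, `degenerate`.
#' @export
compare_to_baseline <- function(series, dose_group,
                                baseline_day = NULL, alpha = 0.05) {
  g <- series[series$dose_group == dose_group, , drop = FALSE]
  if (nrow(g) == 0) {
    stop(sprintf("missing data: no rows for dose group %g", dose_group),
         call. = FALSE)
  }
  if (is.null(baseline_day)) baseline_day <- min(g$day)
  base <- g$concentration[g$day == baseline_day]
  if (length(base) < 2) {
    stop("missing data: need >= 2 replicates on the baseline day",
         call. = FALSE)
  }
  other_days <- sort(setdiff(unique(g$day), baseline_day))
  rows <- lapply(other_days, function(d) {
    y <- g$concentration[g$day == d]
    if (length(y) < 2) {
      stop(sprintf("missing data: need >= 2 replicates on day %g", d),
           call. = FALSE)
    }
    if (sd(base) == 0 && sd(y) == 0) {
      # zero within-group variance: equal means -> no evidence of
      # change, different means -> perfectly separated groups
      degenerate <- TRUE
      if (mean(base) == mean(y)) {
        f <- 0; p <- 1
      } else {
        f <- Inf; p <- 0
      }
    } else {
      dat <- data.frame(conc = c(base, y),
                        grp = factor(rep(c("base", "day"),
                                         c(length(base), length(y)))))
      tab <- anova(lm(conc ~ grp, data = dat))
      f <- tab[["F value"]][1]
      p <- tab[["Pr(>F)"]][1]
      degenerate <- !is.finite(f)
      if (degenerate) { f <- Inf; p <- 0 }
    }
    data.frame(day = d, f_statistic = f, p_value = p,
               significant = p < alpha, degenerate = degenerate)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit first-order dissipation kinetics
#'
#' Log-linear ordinary least squares of `ln(C)` on time: `k` is minus
#' the slope, `DT50 = ln(2) / k`, and the elimination time follows the
#' pharmacokinetic five-half-lives convention,
#' `elimination_time = 5 * DT50`.  A non-positive `k` (no net decline)
#' yields a valid fit flagged `no_dissipation` with infinite DT50.
#'
#' @param concentrations concentrations (any consistent unit); all > 0.
#' @param days time points in days; at least 3.
#' @return an object of class `dissipation_fit` with fields `k` (per
#'   day), `dt50` (days), `elimination_time` (days), `r_squared` (of the
#'   log-linear fit), `intercept_log`, `no_dissipation`.
#' @examples
#' d <- 0:10
#' fit_first_order(10 * exp(-0.315 * d), d)  # DT50 = 2.2 days
#' @export
fit_first_order <- function(concentrations, days) {
  if (length(concentrations) != length(days)) {
    stop("concentrations and days must have equal length", call. = FALSE)
  }
  if (length(days) < 3) {
    stop("need at least 3 time points for a dissipation fit", call. = FALSE)
  }
  if (any(concentrations <= 0)) {
    stop("log-domain error: all concentrations must be > 0 for a first-order fit",
         call. = FALSE)
  }
  fit <- lm(log(concentrations) ~ days)
  slope <- unname(coef(fit)[["days"]])
  k <- -slope
  ss_res <- sum((log(concentrations) - fitted(fit))^2)
  ss_tot <- sum((log(concentrations) - mean(log(concentrations)))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  no_dissipation <- k <= 0
  structure(
    list(k = k,
         dt50 = if (no_dissipation) Inf else log(2) / k,
         elimination_time = if (no_dissipation) Inf else 5 * log(2) / k,
         r_squared = r2,
         intercept_log = unname(coef(fit)[["(Intercept)"]]),
         no_dissipation = no_dissipation),
    class = "dissipation_fit"
  )
}

#' Fit post-peak dissipation of a dose group
#'
#' In inoculated soil the pre-peak phase reflects ongoing biosynthesis,
#' not dissipation, so first-order kinetics are fit only from the
#' group's peak day (of the mean trajectory) onward, on the replicate
#' concentrations.
#'
#' @param series a [soil_timeseries()] data frame.
#' @param dose_group dose group to fit.
#' @param from_peak if `FALSE`, fit on all sampled days instead.
#' @return a [fit_first_order()] result, with attribute `days_used`.
#' @export
fit_dissipation <- function(series, dose_group, from_peak = TRUE) {
  g <- series[series$dose_group == dose_group, , drop = FALSE]
  if (nrow(g) == 0) {
    stop(sprintf("missing data: no rows for dose group %g", dose_group),
         call. = FALSE)
  }
  if (from_peak) {
    means <- aggregate(concentration ~ day, data = g, FUN = mean)
    peak_day <- means$day[which.max(means$concentration)]
    g <- g[g$day >= peak_day, , drop = FALSE]
  }
  if (length(unique(g$day)) < 3) {
    stop("need at least 3 post-peak sampling days for a dissipation fit",
         call. = FALSE)
  }
  fit <- fit_first_order(g$concentration, g$day)
  attr(fit, "days_used") <- sort(unique(g$day))
  fit
}

#' @export
print.dissipation_fit <- function(x, ...) {
  if (x$no_dissipation) {
    cat(sprintf("First-order fit: k = %.4g /day (no net dissipation)\n", x$k))
  } else {
    cat(sprintf(
      "First-order fit: k = %.4g /day, DT50 = %.3g days, eliminated in ~%.3g days (R^2 = %.4f)\n",
      x$k, x$dt50, x$elimination_time, x$r_squared))
  }
  invisible(x)
}
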