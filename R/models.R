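#' Instrument response model for the signal generator
#'
#' Describes how an amount of analyte in soil extract maps to MRM peak
#' areas.  Each component carries a fixed fraction of the total analyte
#' (the B1/B2 split of the commercial standard), a common response factor
#' converts concentration to summed peak area, and a multiplicative
#' matrix suppression factor emulates ionization suppression by
#' co-extracted soil matrix.
#'
#' The default response factor of 37777 area units per ng/g puts
#' simulated summed responses on the same scale as a real matrix-matched
#' soil calibration; the default suppression of 0.9 corresponds to a
#' matrix effect of 90%.
#'
#' @param response_factor summed peak area per ng/g of analyte; > 0.
#' @param subtype_fraction named numeric vector of component fractions;
#'   the fractions of each analyte present must sum to 1 (within 1e-9).
#' @param peak_width_sigma Gaussian peak width (standard deviation) in
#'   minutes.
#' @param baseline_level constant baseline intensity, counts.
#' @param baseline_noise_sd standard deviation of additive Gaussian
#'   baseline noise, counts; >= 0.
#' @param matrix_suppression multiplicative factor in (0, 1]; 1 means no
#'   suppression, 0.9 means responses are reduced to 90% of the
#'   matrix-free value.
#' @param seed integer seed used by generators consuming this model.
#' @return an object of class `signal_model`.
#' @export
signal_model <- function(response_factor = 37777,
                         subtype_fraction = c(PMB1 = 0.7, PMB2 = 0.3),
                         peak_width_sigma = 0.05,
                         baseline_level = 50,
                         baseline_noise_sd = 5,
                         matrix_suppression = 0.9,
                         seed = 1L) {
  if (response_factor <= 0) {
    stop("invalid signal model: response_factor must be > 0", call. = FALSE)
  }
  if (is.null(names(subtype_fraction)) || any(!nzchar(names(subtype_fraction)))) {
    stop("invalid signal model: subtype_fraction must be named", call. = FALSE)
  }
  for (analyte in c("PMB", "PME")) {
    subs <- analyte_subtypes(analyte)
    present <- intersect(subs, names(subtype_fraction))
    if (length(present) > 0 &&
        abs(sum(subtype_fraction[present]) - 1) > 1e-9) {
      stop(sprintf("invalid signal model: %s component fractions must sum to 1",
                   analyte), call. = FALSE)
    }
  }
  if (peak_width_sigma <= 0) {
    stop("invalid signal model: peak_width_sigma must be > 0", call. = FALSE)
  }
  if (baseline_noise_sd < 0) {
    stop("invalid signal model: baseline_noise_sd must be >= 0", call. = FALSE)
  }
  if (matrix_suppression <= 0 || matrix_suppression > 1) {
    stop("invalid signal model: matrix_suppression must be in (0, 1]",
         call. = FALSE)
  }
  structure(
    list(response_factor = response_factor,
         subtype_fraction = subtype_fraction,
         peak_width_sigma = peak_width_sigma,
         baseline_level = baseline_level,
         baseline_noise_sd = baseline_noise_sd,
         matrix_suppression = matrix_suppression,
         seed = as.integer(seed)),
    class = "signal_model"
  )
}

#' Production-decay model for soil polymyxin dynamics
#'
#' Mean concentration of analyte in inoculated soil over time follows a
#' two-exponential (Bateman-type) production-decay curve
#' \deqn{C(t) = background + A (e^{-k_d t} - e^{-k_p t}),}
#' which rises while biosynthesis outpaces dissipation and declines once
#' production fades.  With `production_rate > decay_rate` the curve has a
#' single interior maximum at \eqn{t^* = \ln(k_p/k_d)/(k_p - k_d)}.  This
#' is fixture machinery for generating realistic dose-by-time series, not
#' a mechanistic growth model of the producer population.
#'
#' @param dose_cfu inoculation dose, CFU per 100 g dry soil; >= 0.
#' @param production_amplitude amplitude `A` in mg/kg; >= 0 and intended
#'   to increase with dose.
#' @param background_level background analyte level in control soil,
#'   mg/kg; >= 0.
#' @param production_rate rise rate constant `k_p`, per day; > 0.
#' @param decay_rate decline rate constant `k_d`, per day; > 0 and
#'   strictly less than `production_rate`.
#' @param replicate_cv between-replicate coefficient of variation, in
#'   percent.
#' @param seed integer seed used by generators consuming this model.
#' @return an object of class `dynamics_model`.
#' @export
dynamics_model <- function(dose_cfu,
                           production_amplitude,
                           background_level = 0.0235,
                           production_rate = 0.108,
                           decay_rate = 0.054,
                           replicate_cv = 5,
                           seed = 1L) {
  if (dose_cfu < 0) {
    stop("invalid dynamics model: dose_cfu must be >= 0", call. = FALSE)
  }
  if (production_amplitude < 0) {
    stop("invalid dynamics model: production_amplitude must be >= 0",
         call. = FALSE)
  }
  if (background_level < 0) {
    stop("invalid dynamics model: background_level must be >= 0",
         call. = FALSE)
  }
  if (production_rate <= 0 || decay_rate <= 0) {
    stop("invalid dynamics model: rates must be > 0", call. = FALSE)
  }
  if (production_rate <= decay_rate) {
    stop("invalid dynamics model: production_rate must exceed decay_rate (no interior peak otherwise)",
         call. = FALSE)
  }
  if (replicate_cv < 0) {
    stop("invalid dynamics model: replicate_cv must be >= 0", call. = FALSE)
  }
  structure(
    list(dose_cfu = dose_cfu,
         production_amplitude = production_amplitude,
         background_level = background_level,
         production_rate = production_rate,
         decay_rate = decay_rate,
         replicate_cv = replicate_cv,
         seed = as.integer(seed)),
    class = "dynamics_model"
  )
}

#' Default inoculation doses
#'
#' The six-dose design of the soil incubation study: a control plus five
#' inoculation levels, CFU per 100 g dry soil.
#'
#' @return numeric vector of doses.
#' @export
default_doses <- function() c(0, 1e2, 1e4, 1e6, 1e8, 2e8)

# Production amplitude (mg/kg above background at the day-14 peak of the
# sampling grid, rescaled to the continuous-curve amplitude) as a
# monotone function of dose.  Anchored at the six default doses; other
# doses interpolate linearly in log10(1 + dose).
dose_amplitude <- function(dose) {
  anchors_dose <- c(0, 1e2, 1e4, 1e6, 1e8, 2e8)
  anchors_amp  <- c(0, 0.094, 0.205, 0.222, 0.588, 0.793)
  x <- log10(1 + anchors_dose)
  out <- approx(x, anchors_amp, xout = log10(1 + dose), rule = 2)$y
  out
}

#' Default per-dose dynamics models
#'
#' One [dynamics_model()] per dose, sharing the default rate constants
#' and background, with production amplitude increasing in dose.  The
#' defaults are calibrated so that, without noise, the two highest dose
#' groups peak at day 14 of the standard \{0, 7, 14, 21, 28\} sampling
#' grid, the top group peaks at 0.221 mg/kg, and the control group stays
#' flat at its 0.0235 mg/kg background.
#'
#' @param doses numeric vector of doses, CFU per 100 g dry soil.
#' @param seed integer seed assigned to each model (hierarchically
#'   differentiated by the generator).
#' @param ... further arguments passed to [dynamics_model()].
#' @return named list of `dynamics_model` objects, one per dose.
#' @export
default_dynamics_models <- function(doses = default_doses(), seed = 1L, ...) {
  models <- lapply(seq_along(doses), function(i) {
    d <- doses[i]
    amp <- dose_amplitude(d)
    if (amp > 0) {
      dynamics_model(dose_cfu = d, production_amplitude = amp,
                     seed = seed, ...)
    } else {
      # control soil: flat background, amplitude 0 (rates irrelevant but
      # still validated)
      dynamics_model(dose_cfu = d, production_amplitude = 0,
                     seed = seed, ...)
    }
  })
  names(models) <- format(doses, scientific = TRUE, trim = TRUE)
  models
}

#' @export
print.signal_model <- function(x, ...) {
  cat("Signal model\n")
  cat(sprintf("  response factor : %g area units per ng/g\n", x$response_factor))
  cat(sprintf("  fractions       : %s\n",
              paste(sprintf("%s=%.3g", names(x$subtype_fraction),
                            x$subtype_fraction), collapse = ", ")))
  cat(sprintf("  peak sigma      : %g min\n", x$peak_width_sigma))
  cat(sprintf("  baseline        : %g +/- %g counts\n",
              x$baseline_level, x$baseline_noise_sd))
  cat(sprintf("  matrix factor   : %g\n", x$matrix_suppression))
  invisible(x)
}

#' @export
print.dynamics_model <- function(x, ...) {
  cat(sprintf(
    "Dynamics model: dose %.3g CFU/100 g, A = %.3g mg/kg, k_p = %.3g/d, k_d = %.3g/d, background %.4g mg/kg\n",
    x$dose_cfu, x$production_amplitude, x$production_rate, x$decay_rate,
    x$background_level))
  invisible(x)
}
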