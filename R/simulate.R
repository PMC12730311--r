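#' Simulate an MRM chromatogram
#'
#' Generates a time/intensity trace for one transition of one sample: a
#' Gaussian peak centred at the transition's nominal retention time on a
#' constant baseline, plus optional additive Gaussian baseline noise.
#' The noiseless integral of the peak (above baseline) equals
#' `amount * subtype_fraction * response_factor * matrix_suppression`,
#' so every downstream quantity has a closed-form ground truth.
#'
#' @param transition an [mrm_transition()].
#' @param amount total analyte concentration in ng/g; >= 0.
#' @param model a [signal_model()].
#' @param duration trace length in minutes; must cover the peak centre
#'   +/- 5 peak widths.
#' @param sampling_rate points per minute; > 0.
#' @param sample_id identifier stored on the trace.
#' @param seed integer seed; defaults to the model's seed.  Identical
#'   inputs and seed give bit-identical traces.
#' @return a [chromatogram()].
#' @examples
#' tr <- default_transitions()$PMB1
#' chrom <- simulate_chromatogram(tr, amount = 100, model = signal_model())
#' @export
simulate_chromatogram <- function(transition, amount, model = signal_model(),
                                  duration = 6, sampling_rate = 300,
                                  sample_id = "sample", seed = model$seed) {
  stopifnot(inherits(transition, "mrm_transition"),
            inherits(model, "signal_model"))
  if (!is.numeric(duration) || duration <= 0 ||
      !is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("invalid parameter: duration and sampling_rate must be > 0",
         call. = FALSE)
  }
  if (amount < 0) {
    stop("invalid parameter: amount must be >= 0", call. = FALSE)
  }
  rt <- transition$retention_time
  sigma <- model$peak_width_sigma
  if (rt - 5 * sigma < 0 || rt + 5 * sigma > duration) {
    stop("invalid parameter: duration must cover retention_time +/- 5 peak widths",
         call. = FALSE)
  }
  frac <- model$subtype_fraction[[transition$subtype]]
  if (is.null(frac)) {
    stop(sprintf("signal model carries no fraction for subtype %s",
                 transition$subtype), call. = FALSE)
  }
  time <- seq(0, duration, by = 1 / sampling_rate)
  target_area <- amount * frac * model$response_factor * model$matrix_suppression
  amplitude <- target_area / (sigma * sqrt(2 * pi))
  intensity <- model$baseline_level +
    amplitude * exp(-((time - rt)^2) / (2 * sigma^2))
  if (model$baseline_noise_sd > 0) {
    noise <- withr::with_seed(seed,
      rnorm(length(time), mean = 0, sd = model$baseline_noise_sd))
    intensity <- intensity + noise
  }
  chromatogram(sample_id = sample_id, transition = transition,
               time = time, intensity = intensity)
}

#' Simulate a matrix-matched calibration series
#'
#' Peak areas for a multi-level calibration prepared in blank soil
#' extract.  Areas are proportional to level through the signal model,
#' with multiplicative log-normal noise applied per injection (one noise
#' factor shared by both components of a level/replicate pair, emulating
#' injection-to-injection variation), so the summed response carries the
#' stated coefficient of variation.
#'
#' @param levels calibration levels in ng/g; strictly positive and
#'   strictly increasing.  Default is the seven-level soil series
#'   10--1000 ng/g.
#' @param model a [signal_model()].
#' @param replicates_per_level injections per level.
#' @param noise_cv injection-level coefficient of variation, percent.
#' @param analyte `"PMB"` or `"PME"`; selects which component pair is
#'   simulated.
#' @param seed integer seed; defaults to the model's seed.
#' @return data frame with one row per (level, replicate, subtype):
#'   columns `level`, `replicate`, `subtype`, `area`.
#' @export
simulate_calibration_series <- function(levels = c(10, 20, 40, 100, 200, 500, 1000),
                                        model = signal_model(),
                                        replicates_per_level = 3,
                                        noise_cv = 3,
                                        analyte = c("PMB", "PME"),
                                        seed = model$seed) {
  analyte <- match.arg(analyte)
  if (length(levels) == 0) {
    stop("invalid parameter: levels must be non-empty", call. = FALSE)
  }
  if (any(levels <= 0) || any(diff(levels) <= 0)) {
    stop("invalid parameter: levels must be strictly positive and strictly increasing",
         call. = FALSE)
  }
  if (noise_cv < 0) {
    stop("invalid parameter: noise_cv must be >= 0", call. = FALSE)
  }
  if (replicates_per_level < 1) {
    stop("invalid parameter: replicates_per_level must be >= 1", call. = FALSE)
  }
  subs <- analyte_subtypes(analyte)
  frac <- model$subtype_fraction[subs]
  if (anyNA(frac)) {
    stop(sprintf("signal model carries no fractions for %s", analyte),
         call. = FALSE)
  }
  design <- expand.grid(replicate = seq_len(replicates_per_level),
                        level = levels, KEEP.OUT.ATTRS = FALSE)
  inj_factor <- withr::with_seed(seed,
    lnorm_factors(nrow(design), noise_cv / 100))
  rows <- lapply(seq_len(nrow(design)), function(i) {
    lv <- design$level[i]
    data.frame(level = lv,
               replicate = design$replicate[i],
               subtype = subs,
               area = lv * as.numeric(frac) * model$response_factor *
                 model$matrix_suppression * inj_factor[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Simulate a spike/recovery/matrix-effect validation experiment
#'
#' Generates the replicate table behind an analytical validation panel:
#' pre-extraction spikes (carried through the whole extraction, so they
#' express recovery losses and matrix suppression), post-extraction
#' spikes (matrix suppression only), and solvent standards (neither),
#' each measured on several days with within-day and between-day
#' variability.
#'
#' The `measured` column holds back-calculated concentrations for the
#' pre-extraction arm only: quantification against a matrix-matched
#' calibration cancels the response factor and matrix suppression, so
#' measured values are centred on the nominal level with the stated
#' intra- and inter-day CVs.  The `response` column holds summed peak
#' areas for all three arms and is what recovery and matrix-effect
#' ratios are computed from.
#'
#' Between-day variability is derived from the two CVs as
#' `sqrt(inter_cv^2 - intra_cv^2)`, so `inter_cv` is the pooled CV over
#' all days and must be at least `intra_cv`.
#'
#' @param spike_levels spiking levels in ng/g; default 10, 50, 200.
#' @param n_intra replicates per day; >= 2.
#' @param n_days number of days; >= 2.
#' @param model a [signal_model()].
#' @param intra_cv within-day coefficient of variation, percent.
#' @param inter_cv pooled across-day coefficient of variation, percent;
#'   >= `intra_cv`.
#' @param recovery_mean true extraction recovery, percent (100 = no loss).
#' @param me_mean true matrix effect, percent (100 = no suppression).
#' @param seed integer seed; defaults to the model's seed.
#' @return data frame with columns `day`, `replicate`, `nominal`,
#'   `design_arm` (`"pre_spike"`, `"post_spike"`, `"solvent"`),
#'   `response`, `measured` (NA outside the pre-extraction arm).
#' @export
simulate_validation_experiment <- function(spike_levels = c(10, 50, 200),
                                           n_intra = 3, n_days = 3,
                                           model = signal_model(),
                                           intra_cv = 2.5, inter_cv = 3.3,
                                           recovery_mean = 86, me_mean = 89,
                                           seed = model$seed) {
  if (any(spike_levels <= 0)) {
    stop("invalid parameter: spike_levels must be positive", call. = FALSE)
  }
  if (n_intra < 2 || n_days < 2) {
    stop("invalid parameter: need n_intra >= 2 and n_days >= 2", call. = FALSE)
  }
  if (intra_cv < 0 || inter_cv < 0) {
    stop("invalid parameter: CVs must be >= 0", call. = FALSE)
  }
  if (inter_cv < intra_cv) {
    stop("invalid parameter: inter_cv must be >= intra_cv (it is the pooled CV)",
         call. = FALSE)
  }
  if (recovery_mean <= 0 || me_mean <= 0) {
    stop("invalid parameter: recovery_mean and me_mean must be > 0",
         call. = FALSE)
  }
  between_cv <- sqrt(inter_cv^2 - intra_cv^2) / 100
  arms <- c("pre_spike", "post_spike", "solvent")
  design <- expand.grid(replicate = seq_len(n_intra),
                        day = seq_len(n_days),
                        nominal = spike_levels,
                        design_arm = arms,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # day-level batch factors: one per (arm, level, day)
  cells <- unique(design[, c("design_arm", "nominal", "day")])
  withr::with_seed(seed, {
    cells$day_factor <- lnorm_factors(nrow(cells), between_cv)
    design <- merge(design, cells,
                    by = c("design_arm", "nominal", "day"), sort = TRUE)
    design$rep_factor <- lnorm_factors(nrow(design), intra_cv / 100)
  })
  arm_gain <- c(pre_spike = (recovery_mean / 100) * (me_mean / 100),
                post_spike = me_mean / 100,
                solvent = 1)
  noise <- design$day_factor * design$rep_factor
  design$response <- design$nominal * model$response_factor *
    arm_gain[design$design_arm] * noise
  design$measured <- ifelse(design$design_arm == "pre_spike",
                            design$nominal * noise, NA_real_)
  out <- design[order(design$nominal, design$design_arm, design$day,
                      design$replicate),
                c("day", "replicate", "nominal", "design_arm",
                  "response", "measured")]
  rownames(out) <- NULL
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Simulate a soil concentration time series
#'
#' Dose-by-day-by-replicate analyte concentrations in inoculated soil.
#' Each dose group follows the two-exponential production-decay mean
#' curve of its [dynamics_model()]; replicates scatter around the mean
#' with multiplicative log-normal noise at the model's replicate CV.
#'
#' @param doses inoculation doses, CFU per 100 g dry soil; nonnegative.
#' @param days sampling days; nonnegative, sorted increasing.
#' @param models list of [dynamics_model()] objects, one per dose.
#' @param n_reps replicates per (dose, day).
#' @param seed integer top-level seed; per-dose generators use
#'   hierarchically derived child seeds.
#' @return a `soil_timeseries` data frame with columns `dose_group`,
#'   `day`, `replicate`, `concentration` (mg/kg dry soil).
#' @export
simulate_soil_timeseries <- function(doses = default_doses(),
                                     days = c(0, 7, 14, 21, 28),
                                     models = default_dynamics_models(doses),
                                     n_reps = 3, seed = 1L) {
  if (any(doses < 0)) {
    stop("invalid parameter: doses must be >= 0", call. = FALSE)
  }
  if (any(days < 0) || is.unsorted(days, strictly = TRUE)) {
    stop("invalid parameter: days must be nonnegative and strictly increasing",
         call. = FALSE)
  }
  if (length(models) != length(doses)) {
    stop("invalid parameter: need one dynamics model per dose", call. = FALSE)
  }
  if (n_reps < 1) {
    stop("invalid parameter: n_reps must be >= 1", call. = FALSE)
  }
  rows <- lapply(seq_along(doses), function(i) {
    m <- models[[i]]
    stopifnot(inherits(m, "dynamics_model"))
    mean_conc <- m$background_level + m$production_amplitude *
      (exp(-m$decay_rate * days) - exp(-m$production_rate * days))
    grid <- expand.grid(replicate = seq_len(n_reps), day = days,
                        KEEP.OUT.ATTRS = FALSE)
    factors <- withr::with_seed(child_seed(seed, i),
      lnorm_factors(nrow(grid), m$replicate_cv / 100))
    data.frame(dose_group = doses[i],
               day = grid$day,
               replicate = grid$replicate,
               concentration = rep(mean_conc, each = n_reps) * factors)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  soil_timeseries(out)
}

#' Construct / validate a soil time series table
#'
#' @param x data frame with columns `dose_group`, `day`, `replicate`,
#'   `concentration` (mg/kg dry soil).
#' @return `x` with class `soil_timeseries` prepended.
#' @export
soil_timeseries <- function(x) {
  needed <- c("dose_group", "day", "replicate", "concentration")
  if (!all(needed %in% names(x))) {
    stop(sprintf("soil time series needs columns: %s",
                 paste(needed, collapse = ", ")), call. = FALSE)
  }
  if (any(x$concentration < 0)) {
    stop("soil time series: concentrations must be >= 0", call. = FALSE)
  }
  class(x) <- unique(c("soil_timeseries", class(x)))
  x
}
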