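#' Fit a calibration curve
#'
#' Ordinary least-squares fit of summed peak response on concentration,
#' the standard external matrix-matched calibration.  Unweighted by
#' default; inverse-variance style weights (e.g. `1/x`, `1/x^2`) can be
#' supplied for heteroscedastic data.
#'
#' @param levels concentrations in ng/g; at least 2 distinct values.
#' @param responses summed peak areas, same length as `levels`.
#' @param weights optional fit weights, same length as `levels`.
#' @return an object of class `calibration_curve` with fields `slope`
#'   (area per ng/g), `intercept` (area), `r_squared`, `range_low`,
#'   `range_high` (ng/g), `n_levels` (distinct levels), `n_points`.
#' @examples
#' fit_calibration(c(1, 2, 3), c(3, 5, 7))  # slope 2, intercept 1
#' @export
fit_calibration <- function(levels, responses, weights = NULL) {
  if (length(levels) != length(responses)) {
    stop("levels and responses must have equal length", call. = FALSE)
  }
  if (length(unique(levels)) < 2) {
    stop("degenerate design: need at least 2 distinct calibration levels",
         call. = FALSE)
  }
  dat <- data.frame(level = levels, response = responses)
  fit <- if (is.null(weights)) {
    lm(response ~ level, data = dat)
  } else {
    lm(response ~ level, data = dat, weights = weights)
  }
  ss_res <- sum((dat$response - fitted(fit))^2)
  ss_tot <- sum((dat$response - mean(dat$response))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(
    list(slope = unname(coef(fit)[["level"]]),
         intercept = unname(coef(fit)[["(Intercept)"]]),
         r_squared = r2,
         range_low = min(levels),
         range_high = max(levels),
         n_levels = length(unique(levels)),
         n_points = length(levels)),
    class = "calibration_curve"
  )
}

#' Construct a calibration curve from known coefficients
#'
#' For working with a published calibration line (slope/intercept) when
#' the underlying responses are not available.
#'
#' @param slope area per ng/g; non-zero.
#' @param intercept area.
#' @param r_squared coefficient of determination in `[0, 1]`.
#' @param range_low,range_high validated range, ng/g.
#' @param n_levels number of calibration levels.
#' @return a `calibration_curve`.
#' @export
calibration_curve <- function(slope, intercept, r_squared = NA_real_,
                              range_low = 10, range_high = 1000,
                              n_levels = 7) {
  if (slope == 0) stop("degenerate curve: slope must be non-zero", call. = FALSE)
  if (n_levels < 2) stop("calibration curve needs n_levels >= 2", call. = FALSE)
  if (range_low >= range_high) {
    stop("calibration curve needs range_low < range_high", call. = FALSE)
  }
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1)) {
    stop("r_squared must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(slope = slope, intercept = intercept, r_squared = r_squared,
         range_low = range_low, range_high = range_high,
         n_levels = n_levels, n_points = NA_integer_),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration: y = %.6g x %s %.6g  (R^2 = %s, range %g-%g ng/g, %d levels)\n",
              x$slope, ifelse(x$intercept < 0, "-", "+"), abs(x$intercept),
              ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared)),
              x$range_low, x$range_high, x$n_levels))
  invisible(x)
}

#' Sum component responses of a calibration table
#'
#' Collapses the per-subtype rows of [simulate_calibration_series()] (or
#' user data in the same schema) to one summed response per
#' level/replicate, the quantity the calibration is fit on.
#'
#' @param tbl data frame with columns `level`, `replicate`, `subtype`,
#'   `area`.
#' @param analyte `"PMB"` or `"PME"`.
#' @return data frame with columns `level`, `replicate`, `response`.
#' @export
sum_calibration_responses <- function(tbl, analyte = c("PMB", "PME")) {
  analyte <- match.arg(analyte)
  subs <- analyte_subtypes(analyte)
  tbl <- tbl[tbl$subtype %in% subs, , drop = FALSE]
  if (nrow(tbl) == 0) {
    stop(sprintf("no %s rows in calibration table", analyte), call. = FALSE)
  }
  got <- tapply(tbl$subtype, interaction(tbl$level, tbl$replicate, drop = TRUE),
                function(s) length(unique(s)))
  if (any(got < length(subs))) {
    stop("incomplete measurement: some level/replicate pairs lack a component",
         call. = FALSE)
  }
  agg <- aggregate(area ~ level + replicate, data = tbl, FUN = sum)
  names(agg)[names(agg) == "area"] <- "response"
  agg[order(agg$level, agg$replicate), , drop = FALSE]
}

#' Back-calculate a concentration from a response
#'
#' Inverts the calibration line: `x = (response - intercept) / slope`.
#' Results outside the validated range are annotated, never clipped.
#'
#' @param curve a `calibration_curve`.
#' @param response summed peak area.
#' @return numeric concentration in ng/g with attribute `flags`, a
#'   character vector that may contain `"below_range"` / `"above_range"`.
#' @export
back_calculate <- function(curve, response) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) {
    stop("degenerate curve: zero slope", call. = FALSE)
  }
  conc <- (response - curve$intercept) / curve$slope
  flags <- character(0)
  if (!is.na(curve$range_low) && any(conc < curve$range_low)) {
    flags <- c(flags, "below_range")
  }
  if (!is.na(curve$range_high) && any(conc > curve$range_high)) {
    flags <- c(flags, "above_range")
  }
  attr(conc, "flags") <- flags
  conc
}

#' Estimate detection and quantification limits from signal-to-noise
#'
#' LOD and LOQ are defined at signal-to-noise ratios of 3 and 10.  Given
#' the S/N measured at one known low concentration, both limits follow
#' by linear S/N extrapolation:
#' `LOD = concentration * 3 / sn`, `LOQ = concentration * 10 / sn`, so
#' the LOQ/LOD ratio is 10/3 by construction.
#'
#' @param concentration concentration (ng/g) at which `sn` was measured.
#' @param sn measured signal-to-noise ratio; > 0.
#' @param curve optional `calibration_curve`; if supplied, a warning is
#'   issued when `concentration` lies outside its validated range.
#' @return list with fields `lod` and `loq` (ng/g).
#' @examples
#' estimate_lod_loq(10, sn = 30)  # lod 1, loq 10/3
#' @export
estimate_lod_loq <- function(concentration, sn, curve = NULL) {
  if (!is.numeric(sn) || sn <= 0) {
    stop("invalid measurement: signal-to-noise must be > 0", call. = FALSE)
  }
  if (concentration <= 0) {
    stop("invalid measurement: concentration must be > 0", call. = FALSE)
  }
  if (!is.null(curve) &&
      (concentration < curve$range_low || concentration > curve$range_high)) {
    warning("S/N reference concentration lies outside the calibrated range")
  }
  list(lod = concentration * 3 / sn, loq = concentration * 10 / sn)
}

#' Quantify a sample from its component chromatograms
#'
#' The full per-sample pipeline: integrate both component peaks, sum
#' their areas, back-calculate against the calibration curve, convert
#' ng/g to mg/kg, and flag the result against the detection limits and
#' validated range.
#'
#' @param chroms list of [chromatogram()] objects covering both
#'   components of the analyte.
#' @param curve a `calibration_curve` fit on summed response.
#' @param analyte `"PMB"` or `"PME"`.
#' @param rt_halfwidth half-width of the integration window, minutes,
#'   centred on each transition's nominal retention time.
#' @param lod,loq optional limits in ng/g used to set the `below_LOD` /
#'   `below_LOQ` flags.
#' @return an object of class `quant_result` with fields `sample_id`,
#'   `concentration_ng_g`, `concentration_mg_kg`, `component_areas`
#'   (named numeric), `response`, `flags` (character vector drawn from
#'   `below_LOD`, `below_LOQ`, `below_range`, `above_range`).
#' @export
quantify_sample <- function(chroms, curve, analyte = c("PMB", "PME"),
                            rt_halfwidth = 0.25, lod = NULL, loq = NULL) {
  analyte <- match.arg(analyte)
  stopifnot(inherits(curve, "calibration_curve"))
  subs <- analyte_subtypes(analyte)
  labels <- vapply(chroms, function(ch) ch$transition$subtype, character(1))
  if (!all(subs %in% labels)) {
    stop(sprintf("incomplete measurement: chromatograms missing component(s) %s",
                 paste(setdiff(subs, labels), collapse = ", ")), call. = FALSE)
  }
  peaks <- lapply(subs, function(s) {
    ch <- chroms[[which(labels == s)[1]]]
    rt <- ch$transition$retention_time
    integrate_peak(ch, c(rt - rt_halfwidth, rt + rt_halfwidth))
  })
  areas <- vapply(peaks, function(p) p$area, numeric(1))
  names(areas) <- subs
  total <- sum_components(peaks, analyte)
  conc <- back_calculate(curve, total)
  flags <- attr(conc, "flags")
  conc <- as.numeric(conc)
  if (!is.null(lod) && conc < lod) flags <- c(flags, "below_LOD")
  if (!is.null(loq) && conc < loq) flags <- c(flags, "below_LOQ")
  structure(
    list(sample_id = chroms[[1]]$sample_id,
         concentration_ng_g = conc,
         concentration_mg_kg = ng_g_to_mg_kg(conc),
         component_areas = areas,
         response = total,
         flags = unique(flags)),
    class = "quant_result"
  )
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("Sample '%s': %.4g ng/g (%.4g mg/kg)%s\n",
              x$sample_id, x$concentration_ng_g, x$concentration_mg_kg,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]")
              else ""))
  invisible(x)
}
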