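#' Chromatogram container
#'
#' A time/intensity trace for one MRM transition of one sample.
#'
#' @param sample_id sample identifier.
#' @param transition the [mrm_transition()] the trace was acquired on.
#' @param time minutes, strictly increasing.
#' @param intensity counts, finite, same length as `time`.
#' @return an object of class `chromatogram`.
#' @export
chromatogram <- function(sample_id, transition, time, intensity) {
  stopifnot(inherits(transition, "mrm_transition"))
  if (length(time) != length(intensity)) {
    stop("chromatogram: time and intensity must have equal length",
         call. = FALSE)
  }
  if (is.unsorted(time, strictly = TRUE)) {
    stop("chromatogram: time must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(intensity))) {
    stop("chromatogram: intensities must be finite", call. = FALSE)
  }
  structure(
    list(sample_id = sample_id, transition = transition,
         time = as.numeric(time), intensity = as.numeric(intensity)),
    class = "chromatogram"
  )
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("Chromatogram '%s' (%s): %d points, %.2f-%.2f min\n",
              x$sample_id, x$transition$subtype, length(x$time),
              min(x$time), max(x$time)))
  invisible(x)
}

#' Integrate a chromatographic peak
#'
#' Baseline-corrected trapezoidal integration over a retention-time
#' window.  The baseline is the straight line joining the trace at the
#' two window endpoints; the integrand is the intensity above baseline,
#' clipped at zero.  Signal-to-noise is the baseline-corrected peak
#' height divided by the standard deviation of the residual intensity
#' (trace minus the extended baseline line) in two flanking regions,
#' each one window-width wide, on either side of the window.
#'
#' @param chrom a [chromatogram()].
#' @param rt_window numeric length-2, window start/end in minutes; must
#'   lie inside the trace and contain at least 5 points.
#' @return an object of class `peak_measurement` with fields `area`
#'   (intensity x min), `height`, `retention_time` (apex), fields
#'   `signal_to_noise` (`Inf` when the flanking noise SD is zero, `NA`
#'   when no flanking points exist), `noise_sd`, `baseline_slope`,
#'   `baseline_intercept`, `n_points` and `subtype`.
#' @export
integrate_peak <- function(chrom, rt_window) {
  stopifnot(inherits(chrom, "chromatogram"))
  if (length(rt_window) != 2 || rt_window[1] >= rt_window[2]) {
    stop("rt_window must be an increasing pair of minutes", call. = FALSE)
  }
  t <- chrom$time
  y <- chrom$intensity
  if (rt_window[1] < min(t) || rt_window[2] > max(t)) {
    stop("rt_window outside the trace time span", call. = FALSE)
  }
  inside <- t >= rt_window[1] & t <= rt_window[2]
  if (sum(inside) < 5) {
    stop("insufficient data: integration window contains fewer than 5 points",
         call. = FALSE)
  }
  ti <- t[inside]
  yi <- y[inside]
  # straight-line baseline between window endpoints
  n <- length(ti)
  slope <- (yi[n] - yi[1]) / (ti[n] - ti[1])
  intercept <- yi[1] - slope * ti[1]
  corrected <- pmax(yi - (intercept + slope * ti), 0)
  area <- sum(diff(ti) * (corrected[-1] + corrected[-n]) / 2)
  height <- max(yi - (intercept + slope * ti))
  apex <- ti[which.max(yi - (intercept + slope * ti))]
  # flanking baseline regions, each one window-width wide
  w <- rt_window[2] - rt_window[1]
  flank <- (t >= rt_window[1] - w & t < rt_window[1]) |
           (t > rt_window[2] & t <= rt_window[2] + w)
  if (sum(flank) >= 2) {
    resid <- y[flank] - (intercept + slope * t[flank])
    noise_sd <- sd(resid)
    sn <- if (noise_sd == 0) Inf else max(height, 0) / noise_sd
  } else {
    noise_sd <- NA_real_
    sn <- NA_real_
  }
  structure(
    list(area = area,
         height = max(height, 0),
         retention_time = apex,
         signal_to_noise = sn,
         noise_sd = noise_sd,
         baseline_slope = slope,
         baseline_intercept = intercept,
         n_points = n,
         subtype = chrom$transition$subtype),
    class = "peak_measurement"
  )
}

#' @export
print.peak_measurement <- function(x, ...) {
  cat(sprintf(
    "Peak (%s): area %.4g, height %.4g, RT %.3f min, S/N %.3g\n",
    x$subtype, x$area, x$height, x$retention_time, x$signal_to_noise))
  invisible(x)
}

#' Sum component peak areas of a polymyxin analyte
#'
#' Polymyxin B and E are quantified as the sum of the peak areas of
#' their two major components.  Both components must be present; a
#' missing component is an error, never silently treated as zero.
#'
#' @param areas a list of [integrate_peak()] results (or any objects
#'   with `area` and `subtype` fields), or a named numeric vector of
#'   areas keyed by subtype.
#' @param analyte `"PMB"` or `"PME"`.
#' @return total summed area (numeric scalar).
#' @examples
#' sum_components(c(PMB1 = 70000, PMB2 = 30000), "PMB")  # 100000
#' @export
sum_components <- function(areas, analyte = c("PMB", "PME")) {
  analyte <- match.arg(analyte)
  subs <- analyte_subtypes(analyte)
  if (is.numeric(areas)) {
    vals <- areas[subs]
  } else {
    labels <- vapply(areas, function(p) p$subtype, character(1))
    vals <- vapply(subs, function(s) {
      hit <- which(labels == s)
      if (length(hit) == 0) NA_real_ else areas[[hit[1]]]$area
    }, numeric(1))
  }
  if (anyNA(vals)) {
    missing <- subs[is.na(vals)]
    stop(sprintf("incomplete measurement: missing component(s) %s for %s",
                 paste(missing, collapse = ", "), analyte), call. = FALSE)
  }
  sum(vals)
}
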