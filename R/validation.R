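#' Default method-validation acceptance windows
#'
#' Accuracy and matrix effect must fall within 85--115% (inclusive),
#' recovery within 80--120% (inclusive), precision RSD strictly below
#' 15%, and blank interference at most 5% of the target peak area.
#'
#' @return named list of windows used by [evaluate_method()] and
#'   [assess_selectivity()].
#' @export
default_validation_windows <- function() {
  list(accuracy = c(85, 115),
       rsd_max = 15,
       recovery = c(80, 120),
       matrix_effect = c(85, 115),
       selectivity_max = 5)
}

#' Assess selectivity against a blank matrix
#'
#' Interference is acceptable when the blank response at the analyte's
#' retention time is within +/- 5% of the target peak area (inclusive).
#'
#' @param blank_area peak area in the blank at the analyte RT.
#' @param target_area analyte peak area in a spiked sample; > 0.
#' @param max_ratio acceptance bound in percent.
#' @return list with `ratio` (percent) and `pass` (logical).
#' @export
assess_selectivity <- function(blank_area, target_area,
                               max_ratio = default_validation_windows()$selectivity_max) {
  if (!is.numeric(target_area) || target_area <= 0) {
    stop("invalid reference: target_area must be > 0", call. = FALSE)
  }
  ratio <- 100 * blank_area / target_area
  list(ratio = ratio, pass = ratio <= max_ratio)
}

#' Accuracy of replicate measurements
#'
#' @param measured replicate concentrations.
#' @param nominal nominal (spiked) concentration; > 0.
#' @return accuracy in percent: `100 * mean(measured) / nominal`.
#' @export
compute_accuracy <- function(measured, nominal) {
  if (!is.numeric(nominal) || nominal <= 0) {
    stop("invalid parameter: nominal must be > 0", call. = FALSE)
  }
  if (length(measured) < 1) {
    stop("invalid parameter: need at least one replicate", call. = FALSE)
  }
  100 * mean(measured) / nominal
}

#' Precision (relative standard deviation) of replicate measurements
#'
#' Sample (n-1) standard deviation over the mean, in percent.  For
#' inter-day precision pass the replicates of all days pooled.
#'
#' @param measured replicate concentrations; at least 2.
#' @return RSD in percent.
#' @export
compute_precision <- function(measured) {
  if (length(measured) < 2) {
    stop("invalid parameter: need at least 2 replicates", call. = FALSE)
  }
  m <- mean(measured)
  if (m == 0) {
    stop("undefined RSD: mean of replicates is zero", call. = FALSE)
  }
  100 * sd(measured) / m
}

#' Extraction recovery
#'
#' Ratio of the response of a sample spiked before extraction to the
#' response of a matrix blank spiked after extraction at the same
#' nominal level (Matuszewski convention), in percent.
#'
#' @param pre_spike_response summed area, spiked before extraction.
#' @param post_spike_response summed area, spiked after extraction; > 0.
#' @return recovery in percent.
#' @export
compute_recovery <- function(pre_spike_response, post_spike_response) {
  if (!is.numeric(post_spike_response) || any(post_spike_response <= 0)) {
    stop("invalid reference: post-extraction response must be > 0",
         call. = FALSE)
  }
  100 * pre_spike_response / post_spike_response
}

#' Matrix effect
#'
#' Ratio of the analyte response in post-extraction blank matrix to the
#' response in pure solvent at the same nominal level, in percent;
#' values below 100 indicate ionization suppression.
#'
#' @param matrix_response summed area in post-extraction matrix.
#' @param solvent_response summed area in solvent; > 0.
#' @return matrix effect in percent.
#' @export
compute_matrix_effect <- function(matrix_response, solvent_response) {
  if (!is.numeric(solvent_response) || any(solvent_response <= 0)) {
    stop("invalid reference: solvent response must be > 0", call. = FALSE)
  }
  100 * matrix_response / solvent_response
}

#' Build a validation report from a replicate table
#'
#' Computes the full figure-of-merit panel from a replicate table in the
#' schema of [simulate_validation_experiment()]: per spike level,
#' intra-day accuracy and RSD (first day's replicates), inter-day
#' accuracy and RSD (all days pooled, n = days x replicates), recovery
#' (per-day ratio of pre- to post-extraction mean response, mean +/- SD
#' across days) and matrix effect (per-day ratio of post-extraction
#' matrix to solvent mean response, mean +/- SD across days).
#'
#' @param tbl replicate table with columns `day`, `replicate`,
#'   `nominal`, `design_arm`, `response`, `measured`.
#' @return an object of class `validation_report`: a data frame with one
#'   row per level and columns `nominal`, `accuracy_intra`, `rsd_intra`,
#'   `accuracy_inter`, `rsd_inter`, `recovery_mean`, `recovery_sd`,
#'   `me_mean`, `me_sd`.
#' @export
validation_report <- function(tbl) {
  needed <- c("day", "replicate", "nominal", "design_arm", "response",
              "measured")
  if (!all(needed %in% names(tbl))) {
    stop(sprintf("replicate table needs columns: %s",
                 paste(needed, collapse = ", ")), call. = FALSE)
  }
  levels_ <- sort(unique(tbl$nominal))
  first_day <- min(tbl$day)
  rows <- lapply(levels_, function(lv) {
    pre <- tbl[tbl$nominal == lv & tbl$design_arm == "pre_spike", ]
    post <- tbl[tbl$nominal == lv & tbl$design_arm == "post_spike", ]
    solv <- tbl[tbl$nominal == lv & tbl$design_arm == "solvent", ]
    if (nrow(pre) == 0) {
      stop(sprintf("incomplete report: no pre-extraction replicates at %g ng/g", lv),
           call. = FALSE)
    }
    intra <- pre$measured[pre$day == first_day]
    rec <- me <- c(NA_real_, NA_real_)
    if (nrow(post) > 0) {
      by_day <- sort(unique(intersect(pre$day, post$day)))
      r <- vapply(by_day, function(d) {
        compute_recovery(mean(pre$response[pre$day == d]),
                         mean(post$response[post$day == d]))
      }, numeric(1))
      rec <- c(mean(r), sd(r))
    }
    if (nrow(post) > 0 && nrow(solv) > 0) {
      by_day <- sort(unique(intersect(post$day, solv$day)))
      m <- vapply(by_day, function(d) {
        compute_matrix_effect(mean(post$response[post$day == d]),
                              mean(solv$response[solv$day == d]))
      }, numeric(1))
      me <- c(mean(m), sd(m))
    }
    data.frame(nominal = lv,
               accuracy_intra = compute_accuracy(intra, lv),
               rsd_intra = compute_precision(intra),
               accuracy_inter = compute_accuracy(pre$measured, lv),
               rsd_inter = compute_precision(pre$measured),
               recovery_mean = rec[1], recovery_sd = rec[2],
               me_mean = me[1], me_sd = me[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("validation_report", class(out))
  out
}

#' Evaluate a validation report against acceptance windows
#'
#' Classifies every figure of merit at every level against the
#' configured windows.  Accuracy, recovery and matrix-effect windows are
#' inclusive at both ends; the RSD bound is strict ("below 15%").  The
#' method passes overall only if every criterion passes.
#'
#' @param report a [validation_report()] (or a data frame with the same
#'   columns, e.g. a published validation table).
#' @param windows acceptance windows, see
#'   [default_validation_windows()].
#' @return an object of class `method_evaluation`: list with `verdicts`
#'   (data frame: `nominal`, `metric`, `value`, `pass`) and `pass`
#'   (overall logical).
#' @export
evaluate_method <- function(report, windows = default_validation_windows()) {
  needed <- c("nominal", "accuracy_intra", "rsd_intra", "accuracy_inter",
              "rsd_inter", "recovery_mean", "me_mean")
  if (!all(needed %in% names(report))) {
    stop(sprintf("incomplete report: needs columns %s",
                 paste(needed, collapse = ", ")), call. = FALSE)
  }
  if (anyNA(report[needed])) {
    stop("incomplete report: missing values in required columns",
         call. = FALSE)
  }
  in_window <- function(x, w) x >= w[1] & x <= w[2]
  checks <- list(
    accuracy_intra = function(x) in_window(x, windows$accuracy),
    rsd_intra      = function(x) x < windows$rsd_max,
    accuracy_inter = function(x) in_window(x, windows$accuracy),
    rsd_inter      = function(x) x < windows$rsd_max,
    recovery_mean  = function(x) in_window(x, windows$recovery),
    me_mean        = function(x) in_window(x, windows$matrix_effect)
  )
  verdicts <- do.call(rbind, lapply(names(checks), function(metric) {
    data.frame(nominal = report$nominal,
               metric = metric,
               value = report[[metric]],
               pass = checks[[metric]](report[[metric]]))
  }))
  rownames(verdicts) <- NULL
  structure(list(verdicts = verdicts, pass = all(verdicts$pass)),
            class = "method_evaluation")
}

#' @export
print.method_evaluation <- function(x, ...) {
  cat(sprintf("Method validation: %s\n",
              if (x$pass) "PASS (all criteria)" else "FAIL"))
  fails <- x$verdicts[!x$verdicts$pass, ]
  if (nrow(fails) > 0) {
    cat("Failing criteria:\n")
    print(fails, row.names = FALSE)
  }
  invisible(x)
}
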