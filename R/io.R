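#' Read and write chromatogram CSV files
#'
#' Chromatograms are exchanged as CSV with columns `sample_id`,
#' `subtype`, `time_min`, `intensity`, preceded by `#`-prefixed metadata
#' header lines (at least the generator seed when known).  One file may
#' hold several traces (one per sample/subtype pair).
#'
#' @param chroms a single [chromatogram()] or list of them.
#' @param path output file path.
#' @param seed optional integer recorded in the metadata header.
#' @return `write_chromatogram_csv` returns `path` invisibly;
#'   `read_chromatogram_csv` returns a list of data frames split by
#'   sample/subtype (columns `sample_id`, `subtype`, `time_min`,
#'   `intensity`), with the parsed metadata in attribute `metadata`.
#' @export
write_chromatogram_csv <- function(chroms, path, seed = NULL) {
  if (inherits(chroms, "chromatogram")) chroms <- list(chroms)
  tab <- do.call(rbind, lapply(chroms, function(ch) {
    data.frame(sample_id = ch$sample_id,
               subtype = ch$transition$subtype,
               time_min = ch$time,
               intensity = ch$intensity)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  writeLines("# columns: sample_id,subtype,time_min,intensity", con)
  write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chromatogram_csv
#' @export
read_chromatogram_csv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  tab <- read.csv(text = lines[!grepl("^#", lines)],
                  stringsAsFactors = FALSE)
  needed <- c("sample_id", "subtype", "time_min", "intensity")
  if (!all(needed %in% names(tab))) {
    stop(sprintf("chromatogram CSV needs columns: %s",
                 paste(needed, collapse = ", ")), call. = FALSE)
  }
  out <- split(tab, interaction(tab$sample_id, tab$subtype, drop = TRUE))
  attr(out, "metadata") <- meta
  out
}

#' Persist a calibration curve as JSON
#'
#' @param curve a `calibration_curve`.
#' @param path file path.
#' @return `write_calibration_json` returns `path` invisibly;
#'   `read_calibration_json` returns the `calibration_curve`.
#' @export
write_calibration_json <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  jsonlite::write_json(
    list(slope = curve$slope, intercept = curve$intercept,
         r_squared = curve$r_squared, range_low = curve$range_low,
         range_high = curve$range_high, n_levels = curve$n_levels),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_curve(slope = x$slope, intercept = x$intercept,
                    r_squared = x$r_squared, range_low = x$range_low,
                    range_high = x$range_high, n_levels = x$n_levels)
}

#' Read and write soil time-series CSV files
#'
#' Schema: columns `dose_group`, `day`, `replicate`,
#' `concentration_mg_kg`, with `#`-prefixed metadata headers.
#'
#' @param series a [soil_timeseries()] data frame.
#' @param path file path.
#' @param seed optional integer recorded in the metadata header.
#' @return the path (write) or a `soil_timeseries` (read).
#' @export
write_timeseries_csv <- function(series, path, seed = NULL) {
  tab <- data.frame(dose_group = series$dose_group, day = series$day,
                    replicate = series$replicate,
                    concentration_mg_kg = series$concentration)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  writeLines("# columns: dose_group,day,replicate,concentration_mg_kg", con)
  write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries_csv
#' @export
read_timeseries_csv <- function(path) {
  lines <- readLines(path)
  tab <- read.csv(text = lines[!grepl("^#", lines)],
                  stringsAsFactors = FALSE)
  needed <- c("dose_group", "day", "replicate", "concentration_mg_kg")
  if (!all(needed %in% names(tab))) {
    stop(sprintf("time-series CSV needs columns: %s",
                 paste(needed, collapse = ", ")), call. = FALSE)
  }
  soil_timeseries(data.frame(dose_group = tab$dose_group, day = tab$day,
                             replicate = tab$replicate,
                             concentration = tab$concentration_mg_kg))
}

#' Read a risk scenario from a YAML or JSON config
#'
#' Recognized keys: `f_water`, `f_solid`, `rho_solid_kg_m3`,
#' `kp_soil_l_kg` or an `adsorption` block (`qe_ng_g`,
#' `desorption_rate`, `initial_conc_ng_ml`), `pnec_water_ug_l`, and
#' `thresholds` (`low`, `high`).  Missing keys fall back to the
#' loam-soil defaults of [risk_scenario()].
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a [risk_scenario()].
#' @export
read_risk_scenario <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  defaults <- list(f_water = 0.2, f_solid = 0.6, rho_solid_kg_m3 = 2500,
                   pnec_water_ug_l = 0.06)
  get <- function(key) if (!is.null(cfg[[key]])) cfg[[key]] else defaults[[key]]
  adsorption <- default_adsorption()
  kp <- cfg[["kp_soil_l_kg"]]
  if (is.null(kp) && !is.null(cfg$adsorption)) {
    a <- cfg$adsorption
    adsorption <- adsorption_datum(
      qe = a$qe_ng_g, desorption_rate = a$desorption_rate,
      initial_conc = if (is.null(a$initial_conc_ng_ml)) NA_real_
                     else a$initial_conc_ng_ml)
  }
  thresholds <- c(low = 0.1, high = 1)
  if (!is.null(cfg$thresholds)) {
    th <- cfg$thresholds
    thresholds <- c(low = as.numeric(th$low), high = as.numeric(th$high))
  }
  risk_scenario(f_water = get("f_water"), f_solid = get("f_solid"),
                rho_solid = get("rho_solid_kg_m3"), kp_soil = kp,
                adsorption = adsorption,
                pnec_water = get("pnec_water_ug_l"),
                thresholds = thresholds)
}

#' Write a risk assessment report
#'
#' Emits the per-(dose, day) RQ table as CSV and, optionally, a JSON
#' summary with the derived partitioning constants.
#'
#' @param assessment a [assess_timeseries()] result.
#' @param csv_path path for the CSV table (`dose_group`, `day`,
#'   `mec_mg_kg`, `rq`, `category`); `NULL` to skip.
#' @param json_path path for the JSON summary; `NULL` to skip.
#' @return invisibly, a list of the paths written.
#' @export
write_risk_report <- function(assessment, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(assessment, "risk_assessment"))
  if (!is.null(csv_path)) {
    write.csv(assessment$table, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(kp_soil_l_kg = assessment$kp_soil,
           k_soil_water = assessment$k_soil_water,
           pnec_soil_mg_kg = assessment$pnec_soil,
           crossings = assessment$crossings),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(list(csv = csv_path, json = json_path))
}
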