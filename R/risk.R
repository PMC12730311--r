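#' Equilibrium adsorption datum
#'
#' Batch adsorption/desorption result used to derive the solid-water
#' distribution coefficient: equilibrium adsorption capacity `Qe` and
#' the fraction of adsorbed analyte released on desorption.
#'
#' @param qe equilibrium adsorption capacity, ng/g; > 0.
#' @param desorption_rate desorbed fraction, in (0, 1); e.g. `4e-4` for
#'   a 0.04% desorption rate.
#' @param initial_conc initial aqueous concentration, ng/mL (metadata;
#'   not used in the derivation).
#' @return an object of class `adsorption_datum`.
#' @export
adsorption_datum <- function(qe, desorption_rate, initial_conc = NA_real_) {
  if (qe <= 0) stop("invalid parameter: qe must be > 0", call. = FALSE)
  if (desorption_rate <= 0 || desorption_rate >= 1) {
    stop("invalid parameter: desorption_rate must be in (0, 1)", call. = FALSE)
  }
  structure(list(qe = qe, desorption_rate = desorption_rate,
                 initial_conc = initial_conc),
            class = "adsorption_datum")
}

#' Derive the solid-water distribution coefficient
#'
#' Reconstructs K_Psoil from batch adsorption data: the equilibrium
#' aqueous concentration is the desorbed fraction of the adsorbed
#' amount, `Ce = desorption_rate * Qe`, so
#' `K_Psoil = Qe / Ce = 1 / desorption_rate` (L/kg).  Note the
#' coefficient therefore depends only on the desorption fraction; `Qe`
#' cancels.
#'
#' @param datum an [adsorption_datum()].
#' @return K_Psoil in L/kg.
#' @examples
#' derive_kp(adsorption_datum(qe = 4599.8, desorption_rate = 4e-4))  # 2500
#' @export
derive_kp <- function(datum) {
  stopifnot(inherits(datum, "adsorption_datum"))
  1 / datum$desorption_rate
}

#' Default loam-soil adsorption datum
#'
#' The polymyxin E loam-soil batch adsorption result used as a
#' structural surrogate for polymyxin B: Qe = 4599.8 ng/g, desorption
#' rate 0.04%, initial aqueous concentration 1000 ng/mL.
#'
#' @return an [adsorption_datum()].
#' @export
default_adsorption <- function() {
  adsorption_datum(qe = 4599.8, desorption_rate = 4e-4, initial_conc = 1000)
}

#' Risk assessment scenario
#'
#' Bundles the equilibrium-partitioning constants of the TGD
#' (Technical Guidance Document) soil compartment: phase volume
#' fractions, solid density, the solid-water distribution coefficient
#' (given directly or derived from adsorption data), the aquatic
#' predicted no-effect concentration, and the risk-tier thresholds.
#' Defaults are the loam-soil values: `F_water = 0.2`, `F_solid = 0.6`,
#' `rho_solid = 2500` kg/m^3, `K_Psoil = 2500` L/kg (derived from
#' [default_adsorption()]), `PNEC_water = 0.06` ug/L.
#'
#' @param f_water volume fraction of the water phase, in `[0, 1]`.
#' @param f_solid volume fraction of the solid phase, in `[0, 1]`.
#' @param rho_solid soil solid density, kg/m^3; > 0.
#' @param kp_soil solid-water distribution coefficient, L/kg; >= 0.  If
#'   `NULL`, derived from `adsorption`.
#' @param adsorption an [adsorption_datum()] used when `kp_soil` is
#'   `NULL`.
#' @param pnec_water aquatic predicted no-effect concentration, ug/L;
#'   > 0.
#' @param thresholds risk-tier boundaries: RQ below `low` is low risk,
#'   RQ above `high` is high risk, in between (inclusive) is medium.
#' @return an object of class `risk_scenario`.
#' @export
risk_scenario <- function(f_water = 0.2, f_solid = 0.6, rho_solid = 2500,
                          kp_soil = NULL, adsorption = default_adsorption(),
                          pnec_water = 0.06,
                          thresholds = c(low = 0.1, high = 1)) {
  if (f_water < 0 || f_water > 1 || f_solid < 0 || f_solid > 1) {
    stop("invalid scenario: phase fractions must be in [0, 1]", call. = FALSE)
  }
  if (rho_solid <= 0) {
    stop("invalid scenario: rho_solid must be > 0", call. = FALSE)
  }
  if (is.null(kp_soil)) kp_soil <- derive_kp(adsorption)
  if (kp_soil < 0) {
    stop("invalid scenario: kp_soil must be >= 0", call. = FALSE)
  }
  if (pnec_water <= 0) {
    stop("invalid scenario: pnec_water must be > 0", call. = FALSE)
  }
  if (!all(c("low", "high") %in% names(thresholds)) ||
      thresholds[["low"]] <= 0 || thresholds[["high"]] <= thresholds[["low"]]) {
    stop("invalid scenario: thresholds must satisfy 0 < low < high",
         call. = FALSE)
  }
  structure(
    list(f_water = f_water, f_solid = f_solid, rho_solid = rho_solid,
         kp_soil = kp_soil, pnec_water = pnec_water,
         thresholds = thresholds, adsorption = adsorption),
    class = "risk_scenario"
  )
}

#' Bulk soil-water partition coefficient
#'
#' `K_soil_water = F_water + F_solid * K_Psoil * rho_solid / 1000`
#' (dimensionless, TGD soil compartment).
#'
#' @param scenario a [risk_scenario()].
#' @return dimensionless partition coefficient.
#' @examples
#' k_soil_water(risk_scenario())  # 3750.2
#' @export
k_soil_water <- function(scenario) {
  stopifnot(inherits(scenario, "risk_scenario"))
  scenario$f_water +
    scenario$f_solid * scenario$kp_soil * scenario$rho_solid / 1000
}

#' Predicted no-effect concentration in soil
#'
#' `PNEC_soil = PNEC_water * K_soil_water`, with PNEC_water in ug/L and
#' the result in mg/kg dry soil; the explicit factor of 1000 converts
#' ug to mg.
#'
#' @param scenario a [risk_scenario()].
#' @return PNEC_soil in mg/kg dry soil.
#' @examples
#' pnec_soil(risk_scenario())  # 0.225012
#' @export
pnec_soil <- function(scenario) {
  scenario$pnec_water * k_soil_water(scenario) / 1000
}

#' Risk quotient
#'
#' `RQ = MEC / PNEC_soil`, the measured environmental concentration over
#' the predicted no-effect concentration, both in mg/kg dry soil.
#'
#' @param mec measured environmental concentration, mg/kg dry soil;
#'   >= 0.
#' @param pnec PNEC_soil, mg/kg dry soil; > 0.
#' @return dimensionless RQ.
#' @export
risk_quotient <- function(mec, pnec) {
  if (!is.numeric(pnec) || any(pnec <= 0)) {
    stop("invalid scenario: PNEC_soil must be > 0", call. = FALSE)
  }
  if (any(mec < 0)) {
    stop("invalid input: MEC must be >= 0", call. = FALSE)
  }
  mec / pnec
}

#' Classify a risk quotient into a three-tier category
#'
#' `RQ < 0.1` is low risk, `0.1 <= RQ <= 1` is medium risk, and
#' `RQ > 1` is high risk; both boundaries belong to the medium tier.
#'
#' @param rq risk quotient(s); >= 0.
#' @param thresholds named vector with `low` and `high` boundaries.
#' @return character vector of `"low"`, `"medium"`, `"high"`.
#' @examples
#' classify_risk(c(0.05, 0.1, 0.984, 1, 1.2))
#' @export
classify_risk <- function(rq, thresholds = c(low = 0.1, high = 1)) {
  if (any(rq < 0)) {
    stop("invalid input: RQ must be >= 0", call. = FALSE)
  }
  out <- ifelse(rq < thresholds[["low"]], "low",
                ifelse(rq > thresholds[["high"]], "high", "medium"))
  as.character(out)
}

#' Risk-quotient trajectory of a soil time series
#'
#' Computes the RQ of the across-replicate mean concentration for every
#' (dose, day) cell, classifies each into a tier, and reports the first
#' sampled day (if any) each dose group enters the medium and high
#' tiers.
#'
#' @param series a [soil_timeseries()] data frame.
#' @param scenario a [risk_scenario()].
#' @return an object of class `risk_assessment`: list with `pnec_soil`
#'   (mg/kg), `k_soil_water`, `kp_soil`, `table` (data frame:
#'   `dose_group`, `day`, `mec_mg_kg`, `rq`, `category`) and `crossings`
#'   (data frame: `dose_group`, `first_medium_day`, `first_high_day`,
#'   `NA` when never crossed).
#' @export
assess_timeseries <- function(series, scenario = risk_scenario()) {
  if (nrow(series) == 0) {
    stop("missing data: empty time series", call. = FALSE)
  }
  stopifnot(inherits(scenario, "risk_scenario"))
  pnec <- pnec_soil(scenario)
  summ <- summarize_timeseries(series)$by_day
  tab <- data.frame(dose_group = summ$dose_group, day = summ$day,
                    mec_mg_kg = summ$mean,
                    rq = risk_quotient(summ$mean, pnec))
  tab$category <- classify_risk(tab$rq, scenario$thresholds)
  crossings <- do.call(rbind, lapply(split(tab, tab$dose_group), function(g) {
    g <- g[order(g$day), ]
    med <- g$day[g$category %in% c("medium", "high")]
    high <- g$day[g$category == "high"]
    data.frame(dose_group = g$dose_group[1],
               first_medium_day = if (length(med)) med[1] else NA_real_,
               first_high_day = if (length(high)) high[1] else NA_real_)
  }))
  rownames(crossings) <- NULL
  structure(
    list(pnec_soil = pnec,
         k_soil_water = k_soil_water(scenario),
         kp_soil = scenario$kp_soil,
         table = tab,
         crossings = crossings),
    class = "risk_assessment"
  )
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat(sprintf(
    "Risk assessment: K_Psoil = %g L/kg, K_soil-water = %g, PNEC_soil = %.3f mg/kg\n",
    x$kp_soil, x$k_soil_water, x$pnec_soil))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}
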