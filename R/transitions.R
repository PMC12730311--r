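#' Define an MRM transition
#'
#' A multiple reaction monitoring (MRM) transition is one precursor ->
#' product ion channel monitored for one polymyxin component.  Polymyxin B
#' and E are each quantified as the sum of their two major components
#' (B1 + B2, E1 + E2), so four channels cover both analytes.
#'
#' @param subtype component label, one of `"PMB1"`, `"PMB2"`, `"PME1"`,
#'   `"PME2"`.
#' @param precursor_mz m/z of the doubly protonated precursor ion.
#' @param product_mz m/z of the quantifier fragment.
#' @param collision_energy collision energy in eV.
#' @param retention_time nominal retention time in minutes.
#' @return an object of class `mrm_transition`.
#' @seealso [default_transitions()]
#' @export
mrm_transition <- function(subtype, precursor_mz, product_mz,
                           collision_energy = 30, retention_time) {
  subtype <- match.arg(subtype, c("PMB1", "PMB2", "PME1", "PME2"))
  if (!is.numeric(precursor_mz) || !is.numeric(product_mz) ||
      product_mz <= 0 || precursor_mz <= product_mz) {
    stop("invalid transition: need precursor_mz > product_mz > 0",
         call. = FALSE)
  }
  if (collision_energy <= 0) {
    stop("invalid transition: collision_energy must be > 0", call. = FALSE)
  }
  if (retention_time <= 0) {
    stop("invalid transition: retention_time must be > 0", call. = FALSE)
  }
  structure(
    list(subtype = subtype,
         precursor_mz = precursor_mz,
         product_mz = product_mz,
         collision_energy = collision_energy,
         retention_time = retention_time),
    class = "mrm_transition"
  )
}

#' Default polymyxin MRM transitions
#'
#' The four quantifier channels for the polymyxin components, all with a
#' collision energy of 30 eV.  The dominant fragment near m/z 101
#' originates from the diaminobutyric acid (Dab) residue shared by all
#' subtypes.  Retention times are nominal values for a short C18 gradient
#' and only anchor the simulated peaks; they carry no analytical claim.
#'
#' @return named list of [mrm_transition()] objects
#'   (`PMB1`, `PMB2`, `PME1`, `PME2`).
#' @export
default_transitions <- function() {
  list(
    PMB1 = mrm_transition("PMB1", 602.25, 100.80, 30, 2.85),
    PMB2 = mrm_transition("PMB2", 595.40, 101.25, 30, 2.78),
    PME1 = mrm_transition("PME1", 585.85, 101.20, 30, 2.70),
    PME2 = mrm_transition("PME2", 578.95, 101.00, 30, 2.62)
  )
}

#' Component subtypes of a polymyxin analyte
#'
#' @param analyte `"PMB"` or `"PME"`.
#' @return character vector of the two component labels.
#' @export
analyte_subtypes <- function(analyte = c("PMB", "PME")) {
  analyte <- match.arg(analyte)
  switch(analyte, PMB = c("PMB1", "PMB2"), PME = c("PME1", "PME2"))
}

#' @export
print.mrm_transition <- function(x, ...) {
  cat(sprintf("MRM transition %s: m/z %.2f > %.2f (CE %g eV, RT %.2f min)\n",
              x$subtype, x$precursor_mz, x$product_mz,
              x$collision_energy, x$retention_time))
  invisible(x)
}
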