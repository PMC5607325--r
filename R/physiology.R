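#' Temperature limitation factor
#'
#' Q10 temperature scaling of physiological rates, referenced to 20
#' degrees C: `Tlim = q10^((T - 20)/10)`. The exact value is used
#' throughout; `rounded = TRUE` reproduces the two-decimal constants
#' sometimes quoted for -1, 24 and 48 degrees C site temperatures.
#'
#' @param q10 Q10 coefficient (> 0); 2 is the conventional default for
#'   benthic metabolic rates.
#' @param temperature_c Temperature in degrees C.
#' @param rounded Round the factor to two decimals.
#' @return Dimensionless multiplier applied to temperature-sensitive rate
#'   bounds.
#' @export
temperature_limitation <- function(q10, temperature_c, rounded = FALSE) {
  if (any(q10 <= 0)) stop("q10 must be > 0")
  tlim <- q10^((temperature_c - 20) / 10)
  if (rounded) tlim <- round(tlim, 2)
  tlim
}

#' Default physiological rule set
#'
#' Literature-derived rate and efficiency ranges used to bound the flows:
#' bacterial growth efficiency, the fraction of bacterial production
#' returned to detritus by viral lysis, chemosynthetic fixation
#' efficiency, burial efficiency, relative DOC efflux, and per
#' taxon-class (macrofauna, megafauna) growth coefficients, net growth
#' efficiency, assimilation efficiency, faecal production, maintenance
#' respiration coefficient, and the biomass-specific respiration rate
#' with its multiplier band. Ranges are dimensionless except
#' `biomass_specific_respiration` and `maintenance_coeff` (d-1).
#'
#' @param biomass_specific_respiration Biomass-specific respiration rate
#'   (d-1) applied to both faunal classes.
#' @return A list of class `physiology_rules`.
#' @export
default_physiology_rules <- function(biomass_specific_respiration = 0.01) {
  rules <- list(
    q10 = 2,
    bge_range = c(0.05, 0.45),
    viral_lysis_range = c(0.30, 0.80),
    chemo_efficiency_range = c(0.10, 0.50),
    burial_efficiency_range = c(0.01, 0.03),
    doc_efflux_range = c(0, 0.1),
    macrofauna = list(
      growth_coeff_range = c(0.01, 0.05),
      nge_range = c(0.30, 0.70),
      ae_range = c(0.20, 0.75),
      faecal_range = c(0.25, 0.80),
      maintenance_coeff = 0.01,
      respiration_multiplier_range = c(0.5, 1.5),
      biomass_specific_respiration = biomass_specific_respiration
    ),
    megafauna = list(
      growth_coeff_range = c(0.0027, 0.014),
      nge_range = c(0.50, 0.70),
      ae_range = c(0.20, 0.75),
      faecal_range = c(0.25, 0.80),
      maintenance_coeff = 0.001,
      respiration_multiplier_range = c(0.5, 1.5),
      biomass_specific_respiration = biomass_specific_respiration
    )
  )
  class(rules) <- "physiology_rules"
  validate_physiology_rules(rules)
  rules
}

validate_physiology_rules <- function(rules) {
  check_range <- function(r, what) {
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2] ||
        r[1] < 0 || r[2] > 10) {
      stop("rule range ", what, " must satisfy 0 <= lo <= hi <= 10")
    }
  }
  if (!is.numeric(rules$q10) || rules$q10 <= 0) stop("q10 must be > 0")
  for (nm in c("bge_range", "viral_lysis_range", "chemo_efficiency_range",
               "burial_efficiency_range", "doc_efflux_range")) {
    check_range(rules[[nm]], nm)
  }
  for (cls in c("macrofauna", "megafauna")) {
    r <- rules[[cls]]
    for (nm in c("growth_coeff_range", "nge_range", "ae_range",
                 "faecal_range", "respiration_multiplier_range")) {
      check_range(r[[nm]], paste(cls, nm, sep = "$"))
    }
    if (r$maintenance_coeff < 0 || r$biomass_specific_respiration <= 0) {
      stop(cls, ": maintenance_coeff must be >= 0 and ",
           "biomass_specific_respiration > 0")
    }
  }
  invisible(rules)
}
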