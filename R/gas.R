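# Headspace-to-porewater gas conversions.

#' Calibrate a gas chromatograph against standards
#'
#' Ordinary least-squares calibration of concentration against peak area
#' using premixed standards. With `through_origin = TRUE` the intercept is
#' fixed at zero (one standard suffices); otherwise both slope and intercept
#' are fit (at least two standards).
#'
#' @param standard_areas Numeric vector of peak areas.
#' @param standard_concs Numeric vector of matching concentrations (any
#'   consistent unit; the slope inherits concentration per area unit).
#' @param through_origin Force a zero intercept. Default `FALSE`.
#' @param analyte Label carried on the result.
#'
#' @return An object of class `gc_calibration` with fields `slope`,
#'   `intercept`, `analyte`, `n`.
#' @examples
#' calibrate_gc(c(1, 2, 4), c(10, 20, 40), through_origin = TRUE)
#' @export
calibrate_gc <- function(standard_areas, standard_concs,
                         through_origin = FALSE, analyte = "analyte") {
  stopifnot(is.numeric(standard_areas), is.numeric(standard_concs),
            length(standard_areas) == length(standard_concs))
  n <- length(standard_areas)
  if (any(standard_concs < 0)) stop("standard concentrations must be >= 0")
  if (n < 2 && !through_origin) stop("need at least 2 standards")
  if (n < 1) stop("need at least 1 standard")
  if (stats::var(standard_areas) == 0 && !(through_origin && n == 1)) {
    stop("degenerate standards: all peak areas identical")
  }
  if (through_origin) {
    fit <- stats::lm(standard_concs ~ 0 + standard_areas)
    slope <- unname(stats::coef(fit)[1])
    intercept <- 0
  } else {
    fit <- stats::lm(standard_concs ~ standard_areas)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
  }
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration slope must be positive; got ", format(slope))
  }
  structure(list(slope = slope, intercept = intercept, analyte = analyte,
                 n = n),
            class = "gc_calibration")
}

#' Apply a GC calibration to peak areas
#'
#' @param cal A [calibrate_gc()] result.
#' @param areas Numeric vector of peak areas.
#' @return Concentrations in the calibration's units.
#' @export
apply_gc_calibration <- function(cal, areas) {
  stopifnot(inherits(cal, "gc_calibration"))
  cal$intercept + cal$slope * areas
}

#' Convert a headspace methane partial pressure to a porewater-equivalent
#' concentration
#'
#' Methane is measured in the headspace and is not assumed to equilibrate
#' with the aqueous phase; the total headspace inventory is expressed per
#' litre of porewater: `n = p * V_headspace / (R * T)` moles, divided by
#' `porosity * V_sediment` litres of porewater. Linear in `p_ch4`.
#'
#' @param p_ch4 Methane partial pressure in atm (vectorised).
#' @param geometry An [incubation_geometry()].
#' @param r_gas Gas constant in L atm / (mol K). Default 0.08206.
#' @return Porewater-equivalent methane, mol per litre porewater.
#' @examples
#' g <- incubation_geometry(0.040, 0.020, porosity = 0.8)
#' headspace_methane_to_porewater(0.1, g)
#' @export
headspace_methane_to_porewater <- function(p_ch4, geometry, r_gas = 0.08206) {
  stopifnot(is_incubation_geometry(geometry))
  if (any(p_ch4 < 0)) stop("p_ch4 must be >= 0")
  pw_vol <- geometry$porosity * geometry$sediment_volume
  if (pw_vol <= 0) stop("porosity * sediment_volume must be > 0")
  n_mol <- p_ch4 * geometry$headspace_volume / (r_gas * geometry$temperature)
  n_mol / pw_vol
}

#' Convert a headspace hydrogen mixing ratio to an aqueous concentration
#'
#' Hydrogen is assumed to equilibrate between headspace and porewater, so
#' the aqueous concentration follows Henry's law:
#' `[H2] = K_H * (ppmv * 1e-6 * total_pressure)`. Linear in the mixing
#' ratio.
#'
#' @param mixing_ratio Hydrogen mixing ratio in ppm by volume (vectorised).
#' @param geometry An [incubation_geometry()]; supplies the total pressure.
#' @param henry_const Henry solubility in mol/(L atm). Default 7.8e-4,
#'   a standard value for H2 near 21 degrees C.
#' @return Aqueous hydrogen, mol/L.
#' @examples
#' g <- incubation_geometry(0.040, 0.020, porosity = 0.8)
#' hydrogen_headspace_to_aqueous(1, g) # 1 ppm -> 0.78 nM
#' @export
hydrogen_headspace_to_aqueous <- function(mixing_ratio, geometry,
                                          henry_const = 7.8e-4) {
  stopifnot(is_incubation_geometry(geometry))
  if (any(mixing_ratio < 0)) stop("mixing_ratio must be >= 0")
  if (henry_const <= 0) stop("henry_const must be > 0")
  henry_const * mixing_ratio * 1e-6 * geometry$total_pressure
}
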