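# Gibbs free energy of hydrogenotrophic methanogenesis and its reversal
# into anaerobic oxidation of methane (AOM).
#
# Reaction: 4 H2 + CO2 -> CH4 + 2 H2O, with unit water activity and aqueous
# concentrations standing in for activities (uncharged species). The
# reaction quotient is Q = [CH4] / ([CO2] [H2]^4), so
#   dG = dG0 + R T ln Q.
# Negative dG: forward (methanogenesis) exergonic. Positive dG: the reverse
# reaction (AOM through reverse methanogenesis) is exergonic.

#' Thermodynamic constants for hydrogenotrophic methanogenesis
#'
#' @param dg0 Standard-state Gibbs free energy of 4H2 + CO2 -> CH4 + 2H2O,
#'   kJ/mol. Default -194.53 (tabulated at 18 degrees C, used unchanged at
#'   the incubation temperature of 21 degrees C).
#' @param r_kj Gas constant, kJ/(mol K). Default 0.0083145.
#' @return An object of class `thermo_constants`.
#' @export
thermo_constants <- function(dg0 = -194.53, r_kj = 0.0083145) {
  if (r_kj <= 0) stop("r_kj must be > 0")
  structure(list(dg0 = dg0, r_kj = r_kj), class = "thermo_constants")
}

#' Reaction conditions for the free-energy calculation
#'
#' Aqueous concentrations and temperature at which the free energy of
#' hydrogenotrophic methanogenesis is evaluated. Fields are vectorised and
#' recycled to a common length.
#'
#' @param ch4_aq,co2_aq,h2_aq Aqueous concentrations, mol/L; all must be
#'   strictly positive (the reaction quotient is undefined at zero).
#' @param temperature Kelvin. Default 294.15 (21 degrees C).
#' @return An object of class `reaction_conditions` (a data.frame).
#' @export
reaction_conditions <- function(ch4_aq, co2_aq, h2_aq, temperature = 294.15) {
  d <- data.frame(ch4_aq = ch4_aq, co2_aq = co2_aq, h2_aq = h2_aq,
                  temperature = temperature)
  if (any(!is.finite(d$ch4_aq)) || any(d$ch4_aq <= 0) ||
      any(!is.finite(d$co2_aq)) || any(d$co2_aq <= 0) ||
      any(!is.finite(d$h2_aq)) || any(d$h2_aq <= 0)) {
    stop("undefined reaction quotient: concentrations must be finite and > 0")
  }
  if (any(d$temperature <= 0)) stop("temperature must be > 0 (kelvin)")
  class(d) <- c("reaction_conditions", "data.frame")
  d
}

#' Gibbs free energy of hydrogenotrophic methanogenesis
#'
#' Evaluates `dG = dG0 + R T ln( [CH4] / ([CO2] [H2]^4) )` in kJ/mol. The
#' logarithm is computed as a sum of logs, so extreme concentration ratios
#' do not overflow.
#'
#' @param cond A [reaction_conditions()] object, or a plain list/data.frame
#'   with fields `ch4_aq`, `co2_aq`, `h2_aq`, `temperature` (mol/L, K).
#' @param const A [thermo_constants()] object.
#' @return dG in kJ/mol (vector).
#' @examples
#' # Q = 1 recovers the standard-state value
#' gibbs_hydrogenotrophic(reaction_conditions(1e-2, 1e-2, 1), thermo_constants())
#' @export
gibbs_hydrogenotrophic <- function(cond, const = thermo_constants()) {
  stopifnot(inherits(const, "thermo_constants"))
  if (!all(c("ch4_aq", "co2_aq", "h2_aq", "temperature") %in% names(cond))) {
    stop("cond must carry ch4_aq, co2_aq, h2_aq, temperature")
  }
  ch4 <- cond$ch4_aq; co2 <- cond$co2_aq; h2 <- cond$h2_aq
  if (any(!is.finite(ch4)) || any(ch4 <= 0) ||
      any(!is.finite(co2)) || any(co2 <= 0) ||
      any(!is.finite(h2)) || any(h2 <= 0)) {
    stop("undefined reaction quotient: concentrations must be finite and > 0")
  }
  lnQ <- log(ch4) - log(co2) - 4 * log(h2)
  const$dg0 + const$r_kj * cond$temperature * lnQ
}

#' Hydrogen threshold between net methanogenesis and net AOM
#'
#' The unique aqueous hydrogen concentration `h2*` at which the free energy
#' of hydrogenotrophic methanogenesis is exactly zero for given methane and
#' carbon dioxide concentrations:
#' `h2* = ( CH4 * exp(dG0 / (R T)) / CO2 )^(1/4)`, evaluated in log space.
#' Below `h2*` the reverse reaction (AOM) is exergonic; above it, forward
#' methanogenesis is.
#'
#' @param ch4_aq,co2_aq Aqueous concentrations, mol/L (vectorised).
#' @param temperature Kelvin. Default 294.15.
#' @param const A [thermo_constants()] object.
#' @return h2* in mol/L.
#' @examples
#' h2_threshold(1e-3, 1e-2) # about 1.3 nM
#' @export
h2_threshold <- function(ch4_aq, co2_aq, temperature = 294.15,
                         const = thermo_constants()) {
  stopifnot(inherits(const, "thermo_constants"))
  if (any(ch4_aq <= 0) || any(co2_aq <= 0)) stop("concentrations must be > 0")
  if (any(temperature <= 0)) stop("temperature must be > 0")
  log_h2 <- (log(ch4_aq) - log(co2_aq) +
               const$dg0 / (const$r_kj * temperature)) / 4
  exp(log_h2)
}

#' Classify the sign of the free energy into a process direction
#'
#' @param dg Free energy, kJ/mol (vectorised).
#' @param dead_band Half-width of the near-equilibrium band, kJ/mol
#'   (>= 0). Default 0: classification by sign alone.
#' @return Character vector with values `"methanogenesis_exergonic"`
#'   (dg < -dead_band), `"aom_exergonic"` (dg > +dead_band), or
#'   `"near_equilibrium"`.
#' @export
classify_direction <- function(dg, dead_band = 0) {
  if (dead_band < 0) stop("dead_band must be >= 0")
  out <- rep("near_equilibrium", length(dg))
  out[dg < -dead_band] <- "methanogenesis_exergonic"
  out[dg > dead_band] <- "aom_exergonic"
  out
}

#' Free-energy series over an incubation
#'
#' Evaluates the free energy of hydrogenotrophic methanogenesis for every
#' record of a [geochem_series()] that has both methane and hydrogen
#' measurements, with CO2 held at a fixed configured concentration.
#' Concentrations below the detection floors are replaced by the floor
#' before evaluation and flagged; records missing either gas are skipped
#' and counted.
#'
#' @param series A [geochem_series()].
#' @param co2_aq Fixed aqueous CO2, mol/L. Default 0.01 (10 mM).
#' @param const A [thermo_constants()] object.
#' @param dead_band Passed to [classify_direction()].
#' @param floor_ch4,floor_h2 Detection floors, mol/L. Defaults 1e-8 and
#'   1e-11.
#' @return A data.frame with columns `day`, `bottle`, `replicate`,
#'   `ch4_aq`, `h2_aq`, `dg`, `direction`, `floored`; the number of skipped
#'   records is attached as attribute `n_skipped`.
#' @export
energy_series <- function(series, co2_aq = 0.01, const = thermo_constants(),
                          dead_band = 0, floor_ch4 = 1e-8, floor_h2 = 1e-11) {
  stopifnot(inherits(series, "geochem_series"))
  r <- series$records
  ok <- !is.na(r$methane) & !is.na(r$hydrogen)
  n_skipped <- sum(!ok)
  r <- r[ok, , drop = FALSE]
  ch4 <- pmax(r$methane, floor_ch4)
  h2 <- pmax(r$hydrogen, floor_h2)
  floored <- (r$methane < floor_ch4) | (r$hydrogen < floor_h2)
  if (nrow(r) == 0) {
    out <- data.frame(day = numeric(), bottle = character(),
                      replicate = integer(), ch4_aq = numeric(),
                      h2_aq = numeric(), dg = numeric(),
                      direction = character(), floored = logical())
  } else {
    dg <- gibbs_hydrogenotrophic(
      list(ch4_aq = ch4, co2_aq = co2_aq, h2_aq = h2,
           temperature = series$geometry$temperature),
      const)
    out <- data.frame(day = r$day, bottle = r$bottle,
                      replicate = r$replicate, ch4_aq = ch4, h2_aq = h2,
                      dg = dg, direction = classify_direction(dg, dead_band),
                      floored = floored, stringsAsFactors = FALSE)
  }
  attr(out, "n_skipped") <- n_skipped
  out
}
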