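#' Incubation bottle geometry
#'
#' Physical description of one sealed microcosm bottle: the headspace and
#' sediment volumes, sediment porosity, incubation temperature and total
#' headspace pressure. These quantities are what convert a gas-phase
#' measurement (partial pressure or mixing ratio) into a porewater-equivalent
#' aqueous concentration.
#'
#' @param headspace_volume Headspace volume in litres.
#' @param sediment_volume Bulk sediment volume in litres.
#' @param porosity Porewater fraction of the bulk sediment volume, in (0, 1].
#' @param temperature Incubation temperature in kelvin. Default 294.15 K
#'   (21 degrees C).
#' @param total_pressure Total headspace pressure in atm. Default 1.
#'
#' @return An object of class `incubation_geometry` (a named list).
#' @examples
#' incubation_geometry(0.040, 0.020, porosity = 0.8)
#' @export
incubation_geometry <- function(headspace_volume, sediment_volume, porosity,
                                temperature = 294.15, total_pressure = 1) {
  stopifnot(is.numeric(headspace_volume), is.numeric(sediment_volume),
            is.numeric(porosity), is.numeric(temperature),
            is.numeric(total_pressure))
  if (headspace_volume <= 0) stop("headspace_volume must be > 0")
  if (sediment_volume <= 0) stop("sediment_volume must be > 0")
  if (porosity <= 0 || porosity > 1) stop("porosity must be in (0, 1]")
  if (temperature <= 0) stop("temperature must be > 0 (kelvin)")
  if (total_pressure <= 0) stop("total_pressure must be > 0 (atm)")
  structure(
    list(headspace_volume = headspace_volume,
         sediment_volume = sediment_volume,
         porosity = porosity,
         temperature = temperature,
         total_pressure = total_pressure),
    class = "incubation_geometry"
  )
}

#' @export
print.incubation_geometry <- function(x, ...) {
  cat("Incubation geometry\n")
  cat(sprintf("  headspace: %.4g L, sediment: %.4g L (porosity %.3g)\n",
              x$headspace_volume, x$sediment_volume, x$porosity))
  cat(sprintf("  temperature: %.2f K, total pressure: %.3g atm\n",
              x$temperature, x$total_pressure))
  invisible(x)
}

is_incubation_geometry <- function(x) inherits(x, "incubation_geometry")
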