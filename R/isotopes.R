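# Carbon isotope bookkeeping for methane pools: mixing, Rayleigh residual
# enrichment under AOM, and inversion of a two-end-member mixture.
#
# Deltas are permil vs VPDB. The default mass balance is linear in delta
# space (amount-weighted mean), which at methane-like delta magnitudes
# differs from the exact ratio-space balance by well under 0.1 permil; the
# exact balance is available via `exact = TRUE`.

.R_VPDB <- 0.0112372

#' Isotope mass balance of mixed methane pools
#'
#' Amount-weighted mean delta of several pools. With `exact = TRUE` the
#' balance is done in isotope-ratio space (13C and 12C amounts mixed
#' separately) instead of the linear delta-space approximation.
#'
#' @param amount Pool sizes (mol or any common unit), all >= 0, total > 0.
#' @param delta Pool deltas, permil vs VPDB.
#' @param exact Use the exact ratio-space balance. Default `FALSE`.
#' @return The mixture delta, permil.
#' @examples
#' mix_delta(c(0.47, 1.36), c(-34.9, -80))
#' @export
mix_delta <- function(amount, delta, exact = FALSE) {
  stopifnot(length(amount) == length(delta))
  if (any(amount < 0)) stop("pool amounts must be >= 0")
  if (any(!is.finite(delta))) stop("pool deltas must be finite")
  total <- sum(amount)
  if (total <= 0) stop("total pool amount must be > 0")
  if (!exact) {
    return(sum(amount * delta) / total)
  }
  ratio <- .R_VPDB * (1 + delta / 1000)
  c13 <- amount * ratio / (1 + ratio)
  c12 <- amount / (1 + ratio)
  (sum(c13) / sum(c12) / .R_VPDB - 1) * 1000
}

#' Rayleigh residual enrichment
#'
#' Delta of the residual pool after kinetically fractionating consumption
#' of a fraction `1 - f_remaining` of it (linearised Rayleigh form):
#' `delta0 + epsilon * ln(f_remaining)`. With `epsilon < 0` (consumer
#' prefers 12C, as in AOM) the residual is progressively 13C-enriched as
#' `f_remaining` falls.
#'
#' @param delta0 Initial delta, permil.
#' @param epsilon Kinetic enrichment factor, permil (negative when the
#'   light isotopologue is consumed preferentially).
#' @param f_remaining Fraction of the pool remaining, in (0, 1].
#' @return Residual delta, permil.
#' @examples
#' rayleigh_residual(-34.9, -12, 0.5)
#' @export
rayleigh_residual <- function(delta0, epsilon, f_remaining) {
  if (any(f_remaining <= 0)) stop("f_remaining must be > 0")
  if (any(f_remaining > 1)) stop("f_remaining must be <= 1")
  delta0 + epsilon * log(f_remaining)
}

#' Biogenic fraction of a methane pool from its delta
#'
#' Inverts two-end-member linear mixing between seed methane and biogenic
#' methane: `f = (delta_obs - delta_seed) / (delta_bio - delta_seed)`.
#' Results are clamped to [0, 1]; values outside that range before
#' clamping are flagged in the `"out_of_range"` attribute.
#'
#' @param delta_obs Observed delta, permil (vectorised).
#' @param delta_seed Seed (added) methane end-member, permil. Default
#'   -34.9.
#' @param delta_bio Biogenic end-member, permil. Default -80.
#' @return Biogenic fraction in [0, 1], with attribute `out_of_range`
#'   (logical vector).
#' @export
biogenic_fraction <- function(delta_obs, delta_seed = -34.9, delta_bio = -80) {
  if (delta_seed == delta_bio) stop("end-members must differ")
  f <- (delta_obs - delta_seed) / (delta_bio - delta_seed)
  oor <- f < 0 | f > 1
  f <- pmin(pmax(f, 0), 1)
  attr(f, "out_of_range") <- oor
  f
}
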