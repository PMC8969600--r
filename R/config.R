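# YAML configuration for an analysis run: bottle geometry, thermodynamic
# constants, phase thresholds, and simulator overrides in one file.

#' Read an analysis configuration file
#'
#' Loads a YAML file with any of the sections `geometry` (fields of
#' [incubation_geometry()]), `thermo` (fields of [thermo_constants()]),
#' `phase_rules` (fields of [phase_rules()]), `co2_mM` (fixed aqueous CO2
#' for the free-energy stage), `seed`, and `simulate` (overrides merged
#' into [sim_config()]: `init`, `kinetics`, `gate`, `sulfur`, `isotopes`,
#' `obs`, `horizon`, `dt`, `n_bottles`). Missing sections fall back to
#' package defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `geometry`, `thermo`, `rules`, `co2_aq`
#'   (mol/L), `seed`, and `sim` (a [sim_config()]).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  geometry <- do.call(incubation_geometry,
                      utils::modifyList(list(headspace_volume = 0.040,
                                             sediment_volume = 0.020,
                                             porosity = 0.8),
                                        cfg$geometry %||% list()))
  thermo <- do.call(thermo_constants, cfg$thermo %||% list())
  rules <- do.call(phase_rules, cfg$phase_rules %||% list())
  seed <- cfg$seed %||% 1L
  sim_args <- cfg$simulate %||% list()
  sim_args$geometry <- geometry
  sim_args$seed <- seed
  sim <- do.call(sim_config, sim_args)
  list(geometry = geometry, thermo = thermo, rules = rules,
       co2_aq = (cfg$co2_mM %||% 10) * 1e-3, seed = seed, sim = sim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
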