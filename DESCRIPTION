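Package: cryptomethane
Title: Thermodynamically Gated Methane Cycling in Sediment Microcosm Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for long-term anoxic sediment microcosm
    incubations that transition from sulfate reduction through cryptic
    methane cycling to net methanogenesis. Converts gas-chromatograph
    headspace measurements to porewater-equivalent concentrations,
    evaluates the Gibbs free energy of hydrogenotrophic methanogenesis
    and the hydrogen threshold at which it reverses into anaerobic
    oxidation of methane, estimates windowed rates and concentration
    plateaus, segments incubations into process phases, performs carbon
    isotope mass balance on methane pools, applies standard 16S amplicon
    quality-control and guild-trajectory summaries, and ships a kinetic
    box-model simulator of a sealed microcosm with a thermodynamic gate
    so every analysis stage can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
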