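Package: sandch4
Title: Methane Biogeochemistry of Permeable Sandy Sediments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Calculation chain for quantifying methane production and
    sea-air emission from shallow permeable (sandy) coastal sediments:
    dissolved-gas solubility (Bunsen coefficients) and percent saturation,
    back-calculation of dissolved concentrations from headspace-equilibrated
    vials, sea-air flux estimation from wind speed and Schmidt numbers,
    flow-through-reactor and slurry production-rate computation,
    stoichiometric closure of methylated-metabolite substrate budgets, and
    single-copy marker-gene normalization of functional-gene read counts.
    Includes seeded synthetic-data generators that emulate multi-site
    surveys, reactor time series, slurry incubations and metagenomic count
    tables so every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
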