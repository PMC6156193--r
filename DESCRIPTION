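Package: symbioflux
Title: Constraint-Based Flux Analysis of Host-Endosymbiont Metabolic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and interrogating multi-compartment
    genome-scale metabolic models of insect hosts and their intracellular
    bacterial symbionts. Reads models from an SBML-FBC subset or a tabular
    reaction-list dialect, merges per-organism models into a three-compartment
    (host + primary symbiont + co-primary symbiont) network joined by
    cost-free transport reactions, constrains host reactions from bacteriocyte
    transcriptome (TPM) levels, and infers fluxes by flux balance analysis
    (FBA) and flux variability analysis (FVA). Downstream analyses classify
    per-compartment metabolite imports and exports, detect symbiont-symbiont
    cross-feeding, account for essential-amino-acid release, compute
    elemental nitrogen ledgers and recycling efficiencies, and estimate the
    host's cost of maintaining each symbiont. A synthetic-data module
    generates toy symbioses with analytically known optima for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
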