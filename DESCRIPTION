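Package: mitofba
Title: Constraint-Based Flux Balance Analysis of a Two-Compartment
    Mitochondrial Metabolic Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building, auditing and perturbing compartmentalised
    constraint-based models of mitochondrial metabolism. Implements flux
    balance analysis (maximise or minimise an objective pseudo-reaction
    subject to steady state S v = 0 and flux bounds) with a built-in
    bounded-variable simplex solver, parsimonious reference flux
    distributions, flux variability analysis, blocked-reaction detection,
    thermodynamically infeasible loop audits under zeroed boundary
    conditions, and in-silico disease simulation by knockdown scans,
    efflux-onset threshold searches and uptake-relief scans, with presets
    for fumarase, succinate dehydrogenase and alpha-ketoglutarate
    dehydrogenase deficiency. Reads and writes models in SBML (Level 2
    kinetic-law bounds and Level 3 FBC-style bounds), constraint tables
    and flux reports as TSV, and ships a programmatically generated
    miniature two-compartment mitochondrial fixture model covering
    glycolysis, the TCA cycle, the electron transport chain with a
    reactive-oxygen branch, the malate-aspartate shuttle and the GABA
    shunt.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
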