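Package: cyanodesign
Title: Growth-Coupled Strain Design for Photoautotrophic Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based strain design for photoautotrophic
    growth-coupled product synthesis in cyanobacteria. Implements exact
    rational elementary-flux-mode enumeration, minimal and constrained
    minimal cut sets with separate day (photoautotrophic) and night
    (glycogen maintenance) desired behaviours, CASOP-style reaction
    scoring, ATP/NADPH balance calculators, an ATP-maintenance by
    yield-threshold intervention sweep, and a frozen alternate-electron-flow
    ATP-drain experiment. Ships a reconstructed five-reaction worked
    example and a parameterised photoautotrophic core model of the
    cyanobacterial electron transport chain, and reads/writes
    stoichiometric models as SBML or a plain TSV dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    xml2
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite,
    withr
Config/testthat/edition: 3
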