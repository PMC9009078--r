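Package: embedshield
Title: Embedded-Cluster Electrostatic Models for Molecular-Crystal NMR
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Construction and evaluation machinery for embedded-cluster
    (QM1/QM2/MM) calculations of solid-state NMR shielding constants in
    molecular crystals.  Builds periodic structure models from CIF data,
    expands space-group symmetry, selects a quantum molecular shell around a
    central asymmetric unit, and surrounds it with a self-consistently
    converged point-charge field mapped from ESP-fitted atomic charges.
    Writes engine input decks and point-charge files, parses shielding
    output, and carries a deterministic analytic shielding backend so the
    whole pipeline runs and is testable without an external quantum engine.
    Includes snapshot averaging with an additive vibrational (DIFF)
    correction, and a linear shielding-to-shift referencing model with error
    statistics that reproduces published benchmark tables for six amino-acid
    crystals from packaged data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, tools
Suggests: testthat (>= 3.0.0), withr, jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
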