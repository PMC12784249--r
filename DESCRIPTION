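Package: gmisr
Title: Genetic Minimal Intervention Sets in Integrated Metabolic-Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerates genetic minimal intervention sets (gMIS): minimal
    combinations of gene knock-outs and knock-ins that abolish biomass
    production in integrated metabolic and signed acyclic regulatory (iMR)
    network models. Gene-protein-reaction rules are merged with up to two
    signed regulatory layers into extended Boolean rules, compiled into
    ON/OFF-split artificial reaction networks, and minimal cut sets are
    enumerated per reaction by exact implicit enumeration of a dual
    mixed-integer program with linear-programming feasibility certificates.
    Per-reaction cut sets are integrated into paired intervention/reaction
    incidence matrices from which genome-level intervention sets are
    enumerated and classified (essential gene, synthetic lethality, tumor
    suppressor gene, synthetic dosage lethality, tumor suppressor gene
    complex). Expression data can be mapped onto the catalogue to predict
    context-specific essential genes and tumor suppressors, with Boolean
    adaptation-mechanism checking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    graphics,
    jsonlite,
    methods,
    quadprog,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
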