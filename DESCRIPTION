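Package: lipidenrich
Title: Structure-Aware Over-Representation Analysis for Lipidomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Over-representation analysis (ORA) of lipid lists driven by
    shorthand lipid nomenclature. Parses shorthand lipid names into a
    hierarchical structural representation (category, class, acyl/alkyl
    chains, double-bond positions, oxygen modifications), enumerates
    structural terms at each nomenclature level (chain compositions,
    sn-resolved chains, carbon and double-bond bins, bond types,
    modifications, optionally conditioned on a category or class), tests
    each term with Fisher's exact or hypergeometric test against a
    reference lipidome, adjusts for multiple testing, and summarises the
    significant terms through exclusive UpSet-style intersections and
    Very Important Lipids (VILs). Includes a synthetic lipidome generator
    with planted enrichment, a phyloXML exporter for the lipidome
    hierarchy, a report bundle writer, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    xml2,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
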