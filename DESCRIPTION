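Package: cobirth
Title: Relative Birth Timing of Receptor-Ligand Gene Pairs
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Dates receptor-ligand interactions on an ordered system of
    phylogenetic branches and asks whether binding partners tend to appear
    together. Interaction lists are reduced to non-redundant receptor /
    first-ligand pairs (with enzyme-chain dating for synthesized ligands),
    classified as ligand-before, ligand-synchronous or ligand-after, and
    compared against analytic and permutation nulls of independent gene
    birth built from genome-wide branch frequencies. Includes family-level
    reduction, branch-distance and correlation summaries, multiple
    correspondence analysis of pair traits, and a synthetic-data generator
    with a planted birth-coupling parameter.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
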