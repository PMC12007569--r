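Package: gatescape
Title: Conformational Landscapes and Ligand Interactions of Rocker-Switch Transporters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of conformational ensembles of two-protomer membrane
    transporters that work by an alternating-access rocker-switch mechanism,
    built around the mitochondrial pyruvate carrier. Computes smooth gate
    coordination-number collective variables over multi-model structure files,
    filters ensembles by model quality, clusters models into conformational
    states with seeded k-medoids and selects representative models, quantifies
    rigid-body helix-bundle rotations between states, and profiles geometric
    protein-ligand interactions including docking-pose clustering with the
    Kelley penalty. Includes a fully synthetic rocker-switch ensemble and
    docking-pose generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    cluster,
    optparse
Config/testthat/edition: 3
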