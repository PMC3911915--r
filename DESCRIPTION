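Package: neuritecomp
Title: Resource-Driven Neurite Outgrowth and Competition on Compartmental Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Multi-compartmental simulation of neurite outgrowth driven by a
    soma-produced growth resource (tubulin). Tubulin is produced in the soma,
    moved into the neuritic tree by diffusion and active transport, decays,
    and is consumed at growth cones where its concentration sets the neurite
    elongation rate. The mesh of cylindrical compartments follows the moving
    growth cones via dynamic split/merge remeshing. The package includes SWC
    morphology import/export, synthetic morphology and growth-trace
    generators, perturbation protocols for studying competition between
    sibling branches, a forced-growth replay mode, and exhaustive grid-search
    fitting of transport parameters to observed growth-cone traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
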