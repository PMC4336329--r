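Package: chemclub
Title: Chemical-Club Network Analysis and Ensemble Classification of hERG
    Inhibition Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing activity-annotated chemical structure
    networks from high-throughput hERG (human ether-a-go-go-related gene
    potassium channel) inhibition screens.  Builds Tanimoto fingerprint
    similarity networks and Murcko scaffold hierarchies, computes the
    activity-thresholded chemical-club coefficient with a label-permutation
    null model, fits an imbalance-corrected ensemble of Winnow and RBF-kernel
    classifiers on balanced batches to produce per-compound hERG Blocker
    Scores and Predictability Scores, and summarises the library as a
    six-class activity-predictability network with connection densities and
    blocker/nonblocker enrichments.  A synthetic fingerprint-library
    generator emulating a diverse screening collection makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    methods,
    igraph,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineR,
    ChemmineOB,
    jsonlite
Config/testthat/edition: 3
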