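Package: phnet
Title: Full-Scale Persistent-Homology Analysis of Functional Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Threshold-free analysis of multichannel electrophysiology
    connectivity networks with persistent homology. Recordings are
    decomposed into canonical frequency bands, converted to
    reciprocal-Pearson-correlation distance matrices, embedded as point
    clouds with ISOMAP, and filtered through the full scale of
    Vietoris-Rips complexes. Persistence diagrams and barcodes summarise
    components, loops and voids across every threshold at once, and
    bottleneck and Wasserstein distances quantify their stability and
    group differences. Includes a seeded synthetic-cohort generator with
    controllable correlation block structure, an independent brute-force
    homology oracle for verification, and an end-to-end pipeline with a
    reproducible run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
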