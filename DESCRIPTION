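Package: catalocavity
Title: Cavity Point-Cloud Matching and Sequence Funnels for
    Flavoenzyme Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for cavity-based discovery of candidate fatty acid
    photodecarboxylases and related flavoenzymes. Implements grid-based
    procreation of physico-chemically annotated active-site point clouds
    around a protein-bound carboxylic-acid ligand, rigid point-cloud
    registration with total-score and bidirectional-overlap filtering and
    automated triage of the flavin orientation and electrostatic
    environment, a BLAST-hit/clustering/conserved-arginine sequence
    funnel, docking-cluster evaluation by the combined |E/d| score, and
    deterministic synthetic-data generators with planted ground truth for
    end-to-end validation of the whole funnel.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    bio3d,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
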