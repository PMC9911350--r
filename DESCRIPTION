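Package: lsdkit
Title: Local Shape Descriptors and Affinity-Based Neuron Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-voxel local shape descriptors (local size,
    center-of-mass offset and coordinate covariance of the object under
    each voxel within a Gaussian or ball window) from labeled 3D electron
    microscopy volumes, generates ground-truth affinity targets over
    configurable voxel neighborhoods, and runs the standard affinity
    post-processing chain: seeded watershed over-segmentation, region
    adjacency graph construction, hierarchical agglomeration and
    threshold extraction, both monolithically and block-wise. Includes
    skeleton-based and voxel-based evaluation metrics (variation of
    information, expected run length, min-cut edit metric) and a
    synthetic fixture generator (spheres, tubes, matched skeletons,
    controllably corrupted affinities) so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
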