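Package: mbo3d
Title: Manifold-Based 3D Genome Reconstruction from Single-Cell Hi-C
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs three-dimensional chromosome structures from sparse,
    noisy single-cell Hi-C contact maps by Euclidean distance matrix (EDM)
    completion, formulated as Riemannian trust-region optimization over
    rank-3 positive semidefinite Gram factorizations. Missing pairwise
    distances are imputed by graph shortest paths over observed contacts and
    backbone edges, and down-weighted in the optimization according to the
    hop count of the imputing path. Includes a classical multidimensional
    scaling (CMDS) baseline, contact-map evaluation metrics (percent correct
    contacts, minimum-distance and connectivity violations), and a full
    simulation harness for validating reconstruction from corrupted distance
    matrices (multiplicative Gaussian noise, uniform random deletion).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
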