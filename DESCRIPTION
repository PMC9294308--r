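Package: dcbc
Title: Distance-Controlled Boundary Coefficient for Brain Parcellation
    Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Evaluates surface-based brain parcellations with the
    distance-controlled boundary coefficient (DCBC): vertex pairs are binned
    by geodesic distance along the cortical mesh so that within-parcel and
    between-parcel functional correlations are compared only between pairs
    of matched spatial separation, removing the bias that spatial
    autocorrelation induces in classical criteria such as global Homogeneity
    and the Silhouette coefficient.  Per-bin correlation differences are
    combined by precision (inverse-variance) weighting.  Includes geodesic
    sphere mesh generation, Dijkstra surface distances with a cutoff,
    rotated icosahedral null parcellations, smooth random functional map
    simulation with autocorrelation calibration, spectral-clustering
    parcellation of functional profiles, and GIFTI surface, label and metric
    file input and output.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    igraph,
    Matrix,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
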