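Package: fracvox
Title: Fractal Dimension and Lacunarity of Voxel Volumes with a
    Posterior-Fossa Tumor Scoring System
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: N-dimensional sliding-window fractal analysis of medical image
    volumes: box-counting fractal dimension and gliding-box lacunarity on
    binary segmentation masks, 4D intensity lacunarity with random
    subsampling, phantom generators with known fractal properties, a
    published three-class histology scoring system for pediatric posterior
    fossa tumors, and the bootstrapped one-vs-rest logistic procedure
    (out-of-bootstrap AUC feature selection, weight averaging, scale
    absorption) that produces such scoring systems, plus interobserver
    agreement statistics (Cohen's kappa, ICC(2,1)).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    graphics,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
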