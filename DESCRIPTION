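Package: cryofield
Title: Ab Initio Heterogeneous Cryo-EM Reconstruction with a Hartley-Space Neural Field
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ab initio heterogeneous reconstruction for cryo-EM single-particle
    and cryo-ET subtilt data. Images are modelled in Hartley space through the
    Fourier slice theorem; an implicit neural field conditioned on per-particle
    latent embeddings (an autodecoder) decodes conformations to density maps;
    poses are estimated by hierarchical search over an SO(3) x R2 grid built on
    the Hopf fibration (HEALPix sphere grid times a circle grid) followed by
    stochastic gradient refinement. Includes CTF simulation, dose and tilt
    weighting for subtomogram averaging, a synthetic-data simulator with
    Gaussian-mixture phantoms, Fourier shell correlation and pose-accuracy
    metrics, and latent-space analysis (PCA, k-means, traversals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
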