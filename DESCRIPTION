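Package: sparsepat
Title: Sparse-View Photoacoustic Tomography Simulation and Deep-Learning Artifact Removal
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for studying sparse-view artifact removal in
    two-dimensional photoacoustic tomography (PAT). Generates random
    piecewise-constant and vessel-like initial-pressure phantoms, propagates
    them through a homogeneous medium with a first-order k-space
    pseudospectral solver (perfectly matched layer, circular transducer
    arrays, calibrated sensor noise), reconstructs artifact-laden images by
    time reversal, and trains a multi-scale dense U-Net post-processing
    network (nested U-Net encoder blocks, dilated dense decoder blocks and a
    full-scale multi-scale head) to remove the sparse-sampling artifacts.
    Includes image-quality metrics (SSIM, PSNR, MAE, MSE), k-fold
    cross-validated training, a parameter/FLOP profiler and a reproducible
    simulation-to-evaluation pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
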