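Package: dbtdeblur
Title: Simulation and Two-Phase CNN Deblurring of Digital Breast Tomosynthesis Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end simulation and restoration pipeline for limited-angle
    digital breast tomosynthesis (DBT). Generates stochastic power-law breast
    phantoms with a prescribed volumetric glandular fraction and optional
    spherical lesions, forward-projects them with an exact Siddon ray tracer
    under a rotating cone-beam geometry, reconstructs full-angle CBCT and
    limited-angle DBT volumes with Hanning-weighted FDK, and trains a two-phase
    convolutional network (a 3D residual network followed by a coronal-plane
    U-Net, with MAE, adversarial WGAN-GP and perceptual losses) to restore the
    frequency components lost to the missing cone. Includes point-spread
    function characterization and MSE/GRMSE/CNR and frequency-domain
    evaluation utilities.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tiff,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
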