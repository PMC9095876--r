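Package: palocal
Title: Deep-Learning-Accelerated Localization Photoacoustic Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation, reconstruction and deep-learning acceleration of
    superresolution localization photoacoustic imaging. Generates synthetic
    vascular phantoms and flowing-absorber frame series emulating volumetric
    optical-resolution photoacoustic microscopy (OR-PAM) and planar
    photoacoustic computed tomography (PACT) acquisitions; detects point
    absorbers with sub-pixel centroid localization and superimposes them into
    sparse or dense localization images; evaluates 2D and 3D PSNR, SSIM and
    multiscale SSIM; and trains conditional-GAN U-Net generators that map
    sparse localization images to dense ones, including the OR-PAM-to-PACT
    transfer-learning schedule. Networks run on a compact reverse-mode
    automatic-differentiation engine with compiled convolution kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    tiff,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'localization.R'
    'metrics.R'
    'autodiff.R'
    'phantom.R'
    'pairs.R'
    'networks.R'
    'training.R'
    'experiments.R'
    'io.R'
    'palocal-package.R'
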