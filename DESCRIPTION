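Package: boldmvpa
Title: Multivariate Decoding of Brain States from BOLD fMRI Timeseries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for TR-level multivariate pattern analysis (MVPA) of
    task fMRI: nuisance regression with a Volterra expansion of rigid-body
    motion parameters, iterative smoothing to a target FWHM, percent
    signal change scaling, polynomial detrending, spherical region-of-
    interest mask construction in millimetre (MNI-style) coordinates,
    cross-validated nonlinear support-vector classification of single
    volumes with feature-weight-map extraction, weight-map reproducibility
    across training-set sizes, cross-subject inference on weight maps
    (one-sample and robust-regression maps with cluster-extent
    thresholding, plus ROI-level tests), and a framewise-displacement
    motion-control classifier. A synthetic BOLD generator with known
    discriminative structure supports end-to-end validation of every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    MASS,
    RNifti,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
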