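Package: freerun5d
Title: Free-Running 5D Whole-Heart Cardiac MRI: Trajectory Design,
    Self-Gating, and Motion-Resolved Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale implementation of fully self-gated five-dimensional
    (x-y-z-cardiac-respiratory) free-running whole-heart cardiovascular
    magnetic resonance. Generates 3D radial spiral phyllotaxis sampling
    patterns with interleaved superior-inferior (SI) self-navigation
    readouts, simulates multi-coil radial k-space of a quasi-periodically
    beating and breathing numerical heart phantom with analytic ground
    truth, extracts cardiac and respiratory motion signals from the SI
    projections by principal component analysis, sorts readouts into
    cardiac/respiratory bins, reconstructs motion-resolved images by
    compressed sensing with total-variation regularization along both
    motion dimensions (ADMM with a Kaiser-Bessel gridding non-uniform
    FFT), and quantifies ventricular function (ejection fraction, chamber
    volumes), left atrial volume index (biplane area-length with Du Bois
    body surface area), image quality (contrast ratio, SNR, variance of
    the Laplacian) and method agreement (Bland-Altman limits of agreement,
    Wilcoxon signed-rank).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
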