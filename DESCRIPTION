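Package: starmrf
Title: Subspace-Constrained Reconstruction of Through-Plane Accelerated
    Stack-of-Stars MR Fingerprinting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative T1/T2 mapping from radial
    (stack-of-stars) magnetic resonance fingerprinting acquisitions that
    are accelerated along the slice (partition) direction with k-t
    CAIPIRINHA sampling.  Includes an extended-phase-graph simulator for
    inversion-prepared FISP fingerprint dictionaries, a temporal-subspace
    low-rank inversion forward model built on Kaiser-Bessel gridding, a
    conjugate-gradient solver for fully sampled data and an ADMM solver
    with locally-low-rank regularization for accelerated data, non-local
    means denoising of subspace coefficient images, dot-product dictionary
    matching, a digital sphere phantom with a full acquisition simulator,
    and agreement statistics between unaccelerated and accelerated
    reconstructions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    RNifti,
    jsonlite,
    withr,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
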