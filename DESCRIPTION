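Package: patgv
Title: Total Generalized Variation Reconstruction for Phase-Contrast Photoacoustic Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-step reconstruction of the initial acoustic pressure in
    photoacoustic tomography with optical phase-contrast (line-integrating)
    detection: frequency-domain back propagation of slice-wise projection
    snapshots followed by total-generalized-variation (TGV) or total-variation
    (TV) regularized inversion of the slice-wise 2D Radon transform with a
    Chambolle-Pock primal-dual algorithm. Includes a filtered back projection
    baseline, a synthetic phantom generator for vessel-like pressure
    distributions, quantitative image-quality metrics (PSNR, SSIM, maximum
    amplitude projections, histogram statistics), and an end-to-end simulation
    pipeline for few-angle tomography experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
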