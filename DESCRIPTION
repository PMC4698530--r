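Package: relaxseg
Title: Joint Segmentation and Classification of Brain MR Images from
    Relaxometry Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for joint segmentation and classification of brain
    magnetic resonance images in the three-dimensional space of estimated
    proton density and relaxation times (rho, T1, T2) rather than on raw
    gray-level intensities. Provides a complex-domain spin-echo forward
    model, per-voxel least-squares relaxometry with the phase concentrated
    out in closed form, Fisher-information and Cramer-Rao lower bound
    covariance computation for the (rho, T1, T2) estimators, and three
    decision criteria of increasing statistical sophistication: a
    variance-weighted distance criterion, a full-covariance Mahalanobis
    criterion, and a spatially regularized refinement driven by
    neighborhood label fractions. A synthetic four-tissue brain phantom,
    intensity-inhomogeneity bias fields, K-means and Euclidean baselines,
    and Dice/Jaccard/detection-rate evaluation support end-to-end
    simulation studies; NIfTI import and export cover real acquisitions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png,
    withr
Config/testthat/edition: 3
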