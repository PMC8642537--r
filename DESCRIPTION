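Package: octaquant
Title: Quantification of Enface OCT Angiography Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies retinal microvasculature on enface optical coherence
    tomography angiography (OCTA) images. Implements vesselness-enhanced
    binarization with a foveal-avascular-zone (FAZ) referenced threshold,
    topology-preserving skeletonization, and the standard skeleton-based
    vascular indices (vessel density, vessel length density, vessel diameter
    index, box-counting fractal dimension, vascular tortuosity index,
    vascular complexity index), together with two distance-map nonperfusion
    measures (capillary nonperfusion and geometric perfusion deficit) with
    FAZ exclusion. Includes a synthetic angiogram and cohort generator with
    exact ground truth, and a clustered two-group comparison (generalized
    estimating equations with exchangeable working correlation, robust
    standard errors, diabetic-retinopathy-stage adjustment and Bonferroni
    correction) for fellow-eye data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    sandwich,
    lmtest,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
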