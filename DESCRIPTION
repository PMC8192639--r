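Package: slicenet
Title: 2.5-D Slice-Submodule Convolutional Networks for Amyloid Status
    Classification from FDG PET Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies amyloid PET positivity from template-space FDG PET
    volumes with a 2.5-D convolutional architecture: one independent 2-D
    convolutional submodule per sagittal, coronal and axial slice, whose
    per-slice sigmoid predictions are fused by a single fully connected
    sigmoid head. Includes pons-based reference-region intensity
    normalization, atlas ROI SUVR quantification with tracer-specific
    positivity rules (florbetapir, PiB, florbetaben), a slice-significance
    interpretation method that intersects per-axis significant slices into a
    Cartesian point cloud and reports atlas regions exceeding a point
    threshold, voxel-wise two-sample t-maps with cluster-extent
    thresholding, classification metrics with a repeated random-split
    protocol, and a synthetic volumetric cohort generator so the full
    pipeline can be exercised without access-restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
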