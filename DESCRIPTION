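Package: priorseg
Title: Spatial-Prior-Augmented 3D Convolutional Networks for Neuroanatomy Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Patch-based 3D fully convolutional segmentation of neuroanatomical
    structures in linearly co-registered T1-weighted-like volumes, augmented
    with efficient registration-derived spatial priors: per-structure working
    volumes (dilated union-minus-intersection of training labels), positive
    volumes (voxels certain to belong to a structure), and voxel coordinate
    channels. Includes random 3D elastic-deformation data augmentation,
    class-balanced patch sampling with early stopping, working-volume
    restricted sliding-window inference with overlap averaging,
    largest-connected-component postprocessing, Dice and modified Hausdorff
    distance evaluation, and a synthetic phantom generator with mirrored
    lateralized structures for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
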