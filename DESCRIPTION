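Package: crestseg
Title: Two-Stage 3D U-Net Segmentation of the Bony Pelvis from CT with
    Mesh-Based Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coarse-to-fine segmentation of the bony pelvis (iliac crest
    donor site) from CT volumes using a cascade of two 3D U-Nets: a first
    network localizes the bone in the full field of view at 160x160x224,
    a second re-segments a cropped region of interest at 256x144x144.
    Includes the full training stack (soft Dice loss, Adam,
    reduce-on-plateau schedule with early stopping, transfer
    initialization of the first stage from the second), post-processing
    of binary masks into surgical-planning-ready triangle meshes
    (binary erosion, Gaussian smoothing, marching cubes), greedy
    mesh-to-voxel rasterization for training targets, cutting-plane
    regions of interest recorded relative to the bone's geometric
    center, mesh-based evaluation metrics (volumetric Dice, symmetric
    average surface distance, symmetric 95th-percentile Hausdorff
    distance), and a procedural pelvis-phantom generator so the whole
    pipeline can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
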