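Package: clemalign
Title: Automated Volume Correlative Light and Electron Microscopy Registration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Registers fluorescence microscopy (FM) z-stacks onto volume
    electron microscopy (EM) stacks using shared landmark organelles.
    Landmarks (typically mitochondria) are segmented in FM with a
    thresholded Laplacian-of-Gaussian filter, surface point clouds are
    sampled from the FM and EM segmentations, downsampled and registered
    with coherent point drift (rigid, affine or nonrigid), and the fitted
    transform warps the FM channels onto the EM grid via inverse-mapping
    affine or 3D thin-plate-spline warping. Includes registration-quality
    metrics (intersected volumes, mesh-centroid distances, characteristic
    lengths, landmark errors), robustness protocols, and a synthetic
    paired-volume generator with known ground truth for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tiff,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
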