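Package: lensroi
Title: ROI Determination and Simulation for Lensless Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automatic region-of-interest (ROI) determination for calcium
    imaging videos recorded with implantable lensless CMOS sensors, where
    out-of-focus light makes conventional cell-segmentation tools
    inapplicable. Implements per-pixel dF/F baselining, a two-pass ROI
    algorithm built from Gaussian adaptive (local) binarization,
    morphological opening and area opening, ROI trace extraction, STFT
    spectral subtraction against a non-ROI noise reference, and PCA +
    k-means activity clustering with silhouette-based model selection.
    Also provides a simulator of lensless point-source calcium datasets
    with known ground truth, replicate detection-accuracy studies, missed
    neuron depth analysis, and partial-least-squares sensitivity analysis
    of the algorithm parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    png,
    jsonlite,
    yaml,
    cluster,
    mixOmics
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
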