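Package: breastdens
Title: Breast Density Estimation from Mammograms and Breast MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies mammographic breast density through five measurement
    pathways: histogram-threshold segmentation of raw digital mammograms (HSM),
    a closed-form linear model on eleven acquisition-header parameters (MATH),
    the FFDM unit's own header estimate (Raddose passthrough), and two-Gaussian
    decomposition of breast MRI voxel-intensity histograms under non-fat-
    suppressed (3DGRE) and fat-suppressed (STIR) protocols. Converts segmented
    areas and voxel counts to glandular, fat and total volumes, and provides
    the method-agreement statistics (Pearson correlation matrices, paired mean
    differences with Benjamini-Hochberg false-discovery-rate control) used to
    compare pathways. Includes seeded phantom generators with known ground
    truth for every pathway and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    optparse,
    png,
    RNifti,
    stats,
    tiff,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
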