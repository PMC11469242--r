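Package: fazmetrics
Title: Inner-Ellipse Shape Biomarkers for the Foveal Avascular Zone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the shape of the foveal avascular zone (FAZ) as
    segmented on en face OCT angiography. Implements six established shape
    descriptors (area, circularity, acircularity, roundness, solidity,
    convexity) and three inner-ellipse biomarkers: the absolute area
    difference between the FAZ and its largest inscribed ellipse, and the
    Hausdorff and Chamfer distances between the two boundaries. Includes
    raster and QuPath GeoJSON ingestion, a synthetic FAZ generator that
    couples capillary-dropout irregularity to a simulated Gensini coronary
    severity score, adjusted Gensini scoring with severity-group mapping,
    and the accompanying cohort statistics: group-difference testing,
    zero-inflated Poisson effect models, SMOTE-balanced binary and ordinal
    logistic prediction with stratified cross-validation, and intergrader
    agreement (Dice, Jaccard, Bland-Altman).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    jsonlite,
    mgcv,
    MASS,
    glmmTMB,
    pROC,
    png,
    tiff,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
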