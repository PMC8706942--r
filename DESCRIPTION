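Package: roistab
Title: ROI-Size Stability Analysis of MRI Radiomic Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the robustness of radiomic texture features
    to the size of the region of interest (ROI) in liver MRI. The package
    simulates cohorts of liver-parenchyma volumes with scanner-specific voxel
    geometry as stationary correlated Gaussian random fields, constructs
    sphere-shaped 3D ROI masks of physical diameter on anisotropic voxel
    grids, extracts 93 IBSI-style radiomic features (first-order, GLCM, GLDM,
    GLRLM, GLSZM and NGTDM families), and identifies ROI-size-robust features
    through pairwise Mann-Whitney U tests with Bonferroni correction and
    overall concordance correlation coefficients (Barnhart's generalization
    of Lin's CCC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
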