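Package: radstab
Title: Stability of PET Radiomic Texture Features Across Reconstruction Settings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Digital-phantom workbench for studying how PET image
    reconstruction settings affect three-dimensional radiomic texture
    features. Generates heterogeneous multi-syringe phantom inserts as
    activity volumes, degrades them with image-space surrogates for
    iterative-reconstruction noise, time-of-flight gain and Gaussian
    post-filtering, extracts 78 IBSI-style texture features from five
    matrix families (GLCM, GLRLM, GLSZM, GLDZM, NGTDM), categorizes
    per-feature stability by coefficient of variation, and applies a
    Friedman rank test to select features that remain able to separate
    homogeneous from heterogeneous uptake regions. Reads and writes
    NIfTI volumes so user-supplied images and masks can be analysed
    with the same machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
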