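Package: morphfit
Title: Morphable-Model Fitting and Validation for 3D Face Shape Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for single-image 3D face-shape recovery built around a PCA
    statistical shape model (3D morphable model). Provides construction of a
    morphable model from a corresponded mesh corpus, scaled-orthographic
    camera fitting of 2D facial landmarks by alternating pose and shape
    estimation, analytic building blocks of articulated (blend-skinned)
    head models and spherical-harmonics illumination with their associated
    loss functions, mesh-to-mesh Hausdorff-style distance validation with
    trimmed similarity ICP registration, and a synthetic-data generator so
    every stage is testable without subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), withr, yaml, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
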