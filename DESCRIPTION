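Package: chronomapr
Title: Mapping and Quantifying Topographic Duration Preferences in fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering and quantifying topographic maps of
    stimulus-duration preference ("chronomaps") in event-related fMRI.
    Implements the two stages used to label duration-selective voxels (a
    GLM with offset-locked regressors and winner-take-all labeling, and a
    one-dimensional Gaussian duration population-receptive-field model with
    coarse-to-fine fitting), metrics that quantify the spatial progression
    of the resulting label maps (weighted relative distances and their
    slopes, preferred-duration profiles, weighted centroids, cross-map
    comparison), duration-tuning analysis of labeled clusters, and venous
    artifact checks. A synthetic BOLD generator plants known chronotopic
    gradients on voxel lattices so every stage can be exercised and
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
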