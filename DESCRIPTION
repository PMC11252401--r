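Package: hippograd
Title: Cross-Species Hippocampal Connectivity Gradients on the Unfolded Flatmap
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spectral analysis of hippocampus-cortex functional coupling in a
    shared unfolded (flatmap) coordinate system, for comparing two primate
    species. Builds Fisher-z connectivity matrices from resting-state style
    time series, embeds them with normalized-angle affinity kernels and
    diffusion maps (including a joint two-species embedding), matches the
    joint gradient against cortico-cortical gradient maps with sparse
    regression, spin-test spatial permutation nulls and threshold-Dice
    combination analysis, estimates the cortical reflection of the two
    intrinsic hippocampal axes by dual regression with reprojection into
    flatmap space, computes a searchlight homology index from hippocampal
    connectivity fingerprints, and quantifies categorical subfield flatmaps.
    Ships a synthetic two-species generator with planted axis and network
    structure so the full pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    MASS,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
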