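Package: lesionflow
Title: Quantification of Lesion Progression in Dermoscopic Image Sequences
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the evolution of pigmented skin lesions
    across registered dermoscopic image sequences. Implements ABCDE-rule
    derived per-frame metrics (asymmetry by mirrored-half structural
    similarity, border gradient sharpness, convexity, cluster-based color
    dispersion, major-axis diameter), unimodality-gated color clustering in
    linear RGB, corner-referenced CIELAB color normalization of frame
    sequences, dense Farneback optical flow with sequence-level vector
    accumulation and radial-expansion summaries, sequence statistics
    (trajectories, first-vs-last deltas, Pearson correlation against
    classifier-confidence series), and a seeded synthetic lesion-progression
    generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    cluster,
    withr,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    yaml
biocViews: Software, Visualization, CellBasedAssays
Config/testthat/edition: 3
RoxygenNote: 7.3.3
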