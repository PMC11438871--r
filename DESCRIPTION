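Package: hipposeq
Title: Hippocampal Ensemble Sequence, Assembly and Population-Geometry Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis stack for hippocampal population recordings on linear
    tracks: direction-specific place-field rate maps and tuning metrics,
    memoryless Bayesian position decoding, detection of population-burst
    frames, ripples and theta cycles, quantification of preplay/replay
    trajectory sequences with within-frame time-bin shuffle nulls
    (weighted correlation, sequence score, jump distances, quadrant
    ratio), frame-ensemble similarity scoring and cosine k-means
    clustering with silhouette model selection, PCA cell-assembly
    detection under the Marcenko-Pastur bound with sleep reactivation
    strength, and population-vector geometry of linear space (track-end
    similarity, symmetric-location warp profile, manifold PCA, pattern
    separation). Includes an inhomogeneous-Poisson synthetic-data
    generator with ground truth so every stage can be validated without
    raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
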