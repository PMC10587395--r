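Package: emodecode
Title: Searchlight Decoding of Emotion and Modality Signals in Simulated
    Event-Related fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates slow event-related fMRI experiments in which emotional
    faces, bodies and voices are presented across two scan sessions, and
    analyses them with the multivoxel pipeline used to ask whether emotion
    representations are modality-specific or supramodal: trial-wise GLM beta
    estimation with a canonical double-gamma HRF, Gaussian Naive Bayes
    searchlight decoding of stimulus modality and emotion (within-modality and
    cross-modal) under leave-one-run-out cross-validation, group-level
    inference (t-tests against chance, Bonferroni/FDR/cluster-extent
    corrections, shared-label permutation testing), and spherical-ROI
    condition profiles with 1 - r representational dissimilarity matrices.
    Ground-truth multivoxel patterns are configurable so that every stage can
    be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
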