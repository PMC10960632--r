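Package: patsim
Title: Pattern Similarity Searchlight Analysis of Neural Distinctiveness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Searchlight-based representational similarity analysis of
    trial-wise fMRI activation patterns, aimed at quantifying item- and
    category-level neural distinctiveness and its age-related decline
    (neural dedifferentiation). Provides a synthetic cohort generator with
    a separable category/item/noise signal model, least-squares-single
    (LSS) trial-wise GLM estimation with a canonical haemodynamic response,
    Fisher-z pattern correlation searchlights, nonparametric cluster-mass
    Monte-Carlo permutation statistics for within- and between-group
    contrasts, partial least squares correlation (PLSC) with permutation
    and bootstrap-ratio inference linking distinctiveness to recognition
    memory, and behavioural scoring with trial-wise distinctiveness-memory
    association analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
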