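Package: catrep
Title: Task-Dependent Category Representations from Epoched EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate pattern analysis of epoched EEG for studying how
    categorization task demands reshape neural category representations.
    Provides epoch conditioning (baseline correction, eye-artifact rejection,
    equalized trial subsampling, time binning, ROI averaging), pairwise
    linear-discriminant decoding time courses with shuffled-label baselines
    and temporal generalization, representational similarity analysis with
    multivariate noise normalization, pseudotrials and cross-validated squared
    Euclidean distances, classical multidimensional scaling of representational
    geometry, cluster-based permutation inference over 1D and 2D domains,
    behavioral scoring (log-linear corrected d-prime, reaction-time filters,
    Bonferroni-corrected paired comparisons, posterior-overlap probabilities),
    template-based functional source statistics via the Haufe activation-pattern
    transform and sign-flip bootstraps, and a synthetic-data generator with
    drift-diffusion behavior and a fully known representational ground truth
    for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    MASS,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
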