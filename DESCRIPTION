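Package: balansite
Title: Two-Way Rebalancing for Imbalanced Protein Modification Site Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting protein carbonylation sites (and other
    residue-centred post-translational modifications) from heavily imbalanced
    training data. Implements distance-based residue (DR) features over
    fixed-length peptide windows, a two-way rebalancing strategy that meets at
    the closed-form optimal sampling scale s = sqrt(m*M) (attention-based
    undersampling of the majority class plus a small generative adversarial
    network that oversamples the minority class), baseline resamplers (random
    undersampling, SMOTE interpolation), a Gaussian-kernel support vector
    machine with pairwise-rank AUC evaluation, stratified cross-validation,
    and seeded synthetic data generators for benchmarking across imbalance
    ratios.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    e1071,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
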