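Package: parsimotif
Title: De Novo Motif Discovery with Parsimonious Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: De novo discovery of transcription factor binding motifs from
    ChIP-seq-like sequence sets using inhomogeneous parsimonious Markov
    models. Per-position parsimonious context trees are selected exactly by
    the Bayesian information criterion via dynamic programming, conditional
    probabilities are estimated with the hyperparameter-free factorized
    sequential normalized maximum likelihood (fsNML) estimator, and motifs
    are discovered under a one-occurrence-per-sequence model by a stochastic
    model-selection algorithm. Includes binding-site prediction with a
    negative-set quantile threshold, a Jensen-Shannon divergence test for
    multiple motif occurrence, fragment-based classification with
    cross-validated AUC, sequence logos and conditional sequence logos, and
    a synthetic benchmark generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
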