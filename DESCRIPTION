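Package: stack4mc
Title: Stacked Deep Ensembles with Dynamic Feature Selection for DNA
    N4-Methylcytosine Site Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts DNA N4-methylcytosine (4mC) sites from 41-bp sequence
    windows. Implements fourteen nucleotide feature encoding schemes
    (positional, composition and physicochemical-correlation families), a
    dynamic feature selection procedure that ranks encodings by
    cross-validated single-encoding accuracy and picks the best prefix
    union per species and model, three small deep base models (a 1-D
    convolutional network, a bidirectional LSTM and a Transformer encoder)
    trained with Adam and gradient clipping, and a three-tier stacked
    probabilistic ensemble (out-of-fold base-model probabilities, two
    gradient-boosted learners, an elastic-net logistic metalearner).
    Includes evaluation metrics, leave-one-out ablation harnesses,
    zero-shot cross-species prediction with feature inheritance, k-mer
    enrichment analysis, and a synthetic motif-planted benchmark
    generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
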