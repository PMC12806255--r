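Package: molddi
Title: Substructure-Attention Graph Neural Networks for Drug-Drug
    Interaction Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug-drug interactions (DDIs) from molecular
    structure. Drugs given as SMILES strings are parsed into attributed
    molecular graphs and encoded by a directed bond-level message-passing
    network whose per-radius readouts are weighted by graph self-adaptive
    pooling and blended by a learned radius attention. A relation-aware
    interaction module co-updates the two drug representations together
    with the interaction-type embedding and scores every atom-centred
    substructure of one drug against the partner drug, yielding both an
    interaction probability and per-atom importance scores for
    interpretation. Includes transductive and inductive (cold-start)
    evaluation protocols with constrained negative sampling, standard
    classification metrics, and a synthetic-data generator that plants
    substructure-pair interaction rules so the whole pipeline is testable
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    Matrix,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
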