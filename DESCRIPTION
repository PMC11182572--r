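Package: dppscreen
Title: Virtual Proteolysis and Machine-Learning Screening of DPP-4
    Inhibitory Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico discovery pipeline for dipeptidyl peptidase IV
    (DPP-4) inhibitory peptides from proteins of known sequence. Proteins
    are digested with rule-based enzyme models (trypsin, chymotrypsin,
    pepsin at two pH regimes, papain, stem bromelain, subtilisin, or
    user-defined cleavage grammars), the released peptides are featurized
    with type-2 (amphiphilic) pseudo amino acid composition, gradient
    boosting and random-forest classifiers are benchmarked under
    stratified five-fold cross-validation, and candidate peptides are
    screened, ranked and retraced to the (protein, enzyme) hydrolysis
    parameters that produce them. A synthetic-data module generates
    labeled peptide sets with planted compositional signal and proteins
    with planted cleavage sites so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    optparse,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
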