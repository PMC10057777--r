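Package: aromapred
Title: Aromatase-Related Protein Prediction from Sequence Composition
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sequence-based classification of aromatase-related (CYP19A1-like)
    proteins with support vector machines. Provides dataset curation
    (annotation-keyword filtering and greedy identity-based redundancy
    reduction), four fixed-length feature encodings of protein sequences
    (amino-acid composition, dipeptide composition, their 420-dimensional
    hybrid, and a 400-dimensional composition of normalized PSSM profiles),
    RBF-kernel SVM training and scoring, stratified five-fold
    cross-validation with accuracy, sensitivity, specificity and Matthews
    correlation coefficient, decision-threshold sweeps and per-sequence
    prediction-score graphs, plus a synthetic sequence/PSSM generator for
    fully reproducible end-to-end testing and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    BiocGenerics,
    Biostrings,
    e1071,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
biocViews: Classification, Proteomics, SupportVectorMachine, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
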