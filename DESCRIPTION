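Package: ltrcurate
Title: Machine-Learning Curation of LTR Retrotransposon Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic curation of LTR retrotransposon (LTR-RT) reference
    libraries. Predicted LTR-RT sequences are labelled as intact or as
    contaminated by nested insertions (cross-superfamily, cross-lineage,
    Class II/TIR transposon) or by length anomalies, using rule-based
    filters for ground truth and trained classifiers (classical ML, a
    fully connected network, a convolutional network) for fast automatic
    curation. Includes a synthetic-sequence simulator that generates
    labelled LTR-RT datasets with recoverable ground truth, k-mer and
    one-hot featurization with PCA reduction, stratified splitting,
    and precision/recall/F1/ROC evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    class,
    e1071,
    MASS,
    rpart,
    randomForest,
    nnet,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
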