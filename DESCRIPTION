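Package: dsite
Title: Dihydrouridine Site Prediction from Fixed-Length RNA Windows
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Predicts dihydrouridine (D) modification sites in RNA from
    fixed-length U-centred sequence windows. Provides eleven sequence-derived
    feature encodings (nucleotide chemical property, one-hot, enhanced nucleic
    acid composition, k-mer and reverse-complement k-mer frequencies,
    mono-/di-/tri-nucleotide composition, accumulated nucleotide frequency,
    electron-ion interaction potential and its pseudo trinucleotide variant),
    probabilistic positive-class oversampling, a uniform interface over five
    classifier families (random forest, support vector machine, k-nearest
    neighbours, logistic regression, multi-layer perceptron), sensitivity /
    specificity / accuracy / Matthews correlation / ROC-AUC evaluation with
    repeated stratified cross-validation, cross-species generalization
    experiments, and a synthetic benchmark generator that emulates the
    composition of the five-species dihydrouridine benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Biostrings,
    class,
    e1071,
    glmnet,
    jsonlite,
    nnet,
    randomForest,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
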