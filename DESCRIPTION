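Package: iatentropy
Title: EEG Entropy Features of Implicit Association Test Processing and
    Exercise Behavior Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline linking EEG nonlinear-dynamics features
    recorded during Implicit Association Test (IAT) processing to
    subsequent exercise behavior. Implements IAT D-score scoring with the
    improved-algorithm trial filters, IPAQ MET-min/week scoring and
    exercise-group assignment, stimulus-locked EEG epoch preprocessing
    (downsampling, zero-phase FIR band-pass, epoching, baseline
    correction, amplitude rejection), seven entropy estimators (singular
    spectrum, approximate, sample, fuzzy, permutation, Hilbert-envelope
    and log-energy entropy) aggregated over five scalp regions and four
    task conditions, task-wise Benjamini-Hochberg FDR-controlled Wilcoxon
    group comparisons, and a four-classifier evaluation protocol with ROC
    analysis and normalized random-forest feature importances. A
    synthetic-cohort generator with a plantable group effect in envelope
    complexity makes every stage testable without access to patient EEG.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    randomForest,
    e1071,
    MASS,
    class,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
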