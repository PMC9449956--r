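Package: faupalsy
Title: Facial Paralysis Severity Classification from Facial Animation Units
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies unilateral facial paralysis into seven severity
    categories (normal plus mild/moderate/severe for each side) from
    tabular facial animation unit (FAU) recordings of six facial
    movements. Raw per-movement FAU activations are transformed into
    animation symmetry indices and rest-difference facial grades, class
    imbalance is handled by a hybrid of random undersampling, SMOTE
    oversampling and decision-threshold moving, and records are
    classified by a two-level ensemble: five movement-specific RBF-kernel
    support vector machines combined by a rule-based majority-vote
    classifier. Includes a synthetic cohort generator emulating
    side-specific, severity-graded asymmetry, per-class one-vs-rest
    evaluation metrics, and repeated cross-validation robustness reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    class,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
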