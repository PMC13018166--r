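Package: hcadbn
Title: Hill-Climbing Optimized Deep Belief Networks for Crop Yield Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Binary classification of maize kernel weight (low < 25 g versus
    high >= 25 g) from plant and ear trait tables. Implements Restricted
    Boltzmann Machines trained by Contrastive Divergence (CD-K) with exact
    small-model enumeration oracles, greedy layer-wise Deep Belief Network
    pre-training with supervised backpropagation fine-tuning, hill-climbing
    hyperparameter search over the network configuration space, the
    accompanying preprocessing chain (normality assessment, power transforms,
    min-max scaling, variance inflation factors), an evaluation and robustness
    suite (class-wise metrics, ROC/AUC, stratified k-fold cross-validation,
    out-of-bag bootstrap, permutation feature sensitivity), and a synthetic
    trait-table generator for end-to-end testing without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nortest,
    car,
    lmtest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
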