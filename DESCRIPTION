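Package: elas
Title: Ensemble Learning with Active Sampling for Imbalanced Clinical Prediction
Version: 0.1.0
Authors@R:
    person("Analytics", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Meta-classifier for imbalanced binary clinical prediction built on
    ranked batch-mode active sampling. A balanced seed of patients initializes a
    base classifier; the most informative pool samples are queried in batches to
    grow a sequence of base classifiers, and the best performers across
    stratified internal-validation folds and seed initializations are averaged
    into an ensemble. Includes clinical tabular preprocessing (one-hot encoding,
    quantile binning, variance filtering), horizon labeling from disease-free
    and overall survival follow-up, three base-learner families (RBF-kernel
    support vector machine, L2-regularized logistic regression, CART) with
    grid-search tuning, a synthetic imbalanced-cohort generator with known
    ground truth, and a repeated-holdout evaluation harness with AUROC and
    AUPRC metrics and paired t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    quadprog,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
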