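Package: mcicascade
Title: Cascaded Multimodal Classification of Mild Cognitive Impairment from
    Language Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction and cascaded late-fusion classification for
    detecting mild cognitive impairment (MCI) from multimodal language data.
    Three language tasks (picture description, silent reading, reading aloud)
    are observed through four modes (speech timing, transcript language,
    eye movements, comprehension responses); mode-level feature vectors feed
    a hierarchy of probabilistic classifiers fused at the feature, mode, task
    or session level. Includes leave-pair-out cross-validation with pairwise
    AUC, a neuropsychological test-score baseline with sign-adjusted Spearman
    correlation analysis, retrospective MCI subtyping, per-participant
    explanation reports, and a synthetic cohort generator that emits raw
    records for every mode so the full pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
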