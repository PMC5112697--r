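Package: pdmedit
Title: Multi-Edit Instance Selection and Decorrelated Neural-Network
    Ensembles for Dysphonia-Based Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Instance selection and ensemble classification for tabular
    biomedical feature data with repeated measurements per subject, such as
    acoustic dysphonia features recorded from people with Parkinson's disease.
    Implements the multi-edit nearest-neighbor (MENN) procedure for removing
    non-discriminative training samples, a closed-form decorrelated ensemble
    of random vector functional link (RVFL) networks solved through the
    hidden-correlation linear system, classical classifier backends (random
    forest, support vector machines, k-nearest neighbors), and subject-aware
    evaluation protocols: leave-one-out, leave-one-subject-out with majority
    voting, and subject-independent cross-validation, together with
    repeated-run summaries and between-algorithm significance tests.
    A subject-clustered synthetic data generator with controllable
    contamination supports simulation studies and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    MASS,
    withr,
    randomForest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
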