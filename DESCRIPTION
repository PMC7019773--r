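Package: cima
Title: Computer-Based Infant Movement Assessment from Body-Part Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Windowed time-frequency assessment of infant spontaneous movements
    for early cerebral palsy (CP) risk screening. Decomposes 12-channel body-part
    pixel trajectories by multivariate empirical mode decomposition (MEMD) and the
    Hilbert-Huang transform into per-scale instantaneous frequency, amplitude and
    inter-channel covariation features over 5-second windows (990 features per
    window), selects predictive features by partial least squares (PLS) regression
    with backward elimination, reduces them to five composite scores classified by
    linear discriminant analysis, and aggregates window labels into a per-video
    proportion of CP risk-related movement periods. Includes a synthetic trajectory
    cohort generator with typical and reduced-variability movement phenotypes, a
    subject-grouped double (nested) cross-validation harness, and diagnostic
    accuracy statistics (sensitivity, specificity, predictive values with
    Clopper-Pearson intervals, ROC/AUC, rank-based group comparisons) together
    with a spatial center-of-motion baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    MASS,
    mixOmics,
    pROC,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
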