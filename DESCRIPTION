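Package: modflux
Title: Dynamic Regulatory Influence Models for Functional Gene Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds cluster-level dynamic models of transcriptional regulation
    from time-course expression data. Functionally coherent gene modules are
    discovered by hierarchical clustering with an enrichment-based coherence
    score, a sparse steady-state influence model between modules is inferred by
    L1-penalized regression with leave-one-time-course-out cross-validation,
    the model is converted to a coupled linear ODE system and calibrated to
    observed trajectories by two-stage simulated annealing, and the result is
    assessed with matrix-randomization nulls, external interaction-set
    validation, and condition-consensus comparison. A synthetic-data generator
    with planted ground-truth models supports download-free testing and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
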