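Package: rdcens
Title: Conformational Ensemble Selection from Steric-Alignment Residual
    Dipolar Couplings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes inter-domain conformational heterogeneity of
    multi-domain proteins from backbone residual dipolar couplings (RDCs)
    measured under steric alignment. Predicts a shape-dependent alignment
    tensor per conformer with a planar-barrier obstruction model,
    back-calculates and ensemble-averages RDCs, selects minimal conformer
    ensembles that collectively fit experimental couplings with a genetic
    algorithm under free-RDC cross-validation, and analyzes the resulting
    inter-domain angle distributions, basin populations and their
    robustness to experimental and tensor-prediction error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
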