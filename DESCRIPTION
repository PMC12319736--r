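Package: bayesrsn
Title: Subject-Level Resting-State Networks via Hierarchical Bayesian Template ICA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Surface-based estimation of individual resting-state networks
    from vertex-wise BOLD time series. Implements empirical population prior
    (template) construction from dual-regression pseudo-sessions, an
    expectation-maximization fit of the hierarchical template-ICA model giving
    vertex-wise Gaussian posterior mean and standard deviation maps per
    network, Bayesian engagement tests with Bonferroni correction,
    winner-takes-all parcellation, DVARS-based contiguous block censoring,
    temporal signal-to-noise mapping, and cohort-level analyses (area-weighted
    connectivity strength, partial Spearman age associations, parcellation
    frequency maps). Includes a synthetic surface-BOLD generator with known
    ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
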