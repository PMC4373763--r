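Package: geldd
Title: Differential Display Analysis of Two-Dimensional Gel Electrophoresis
    Spot Volumes
Version: 0.1.0
Authors@R:
    person("geldd", "authors", email = "geldd@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for two-dimensional gel electrophoresis
    (2DE) differential display. Estimates each spot's intrinsic fold-change
    variability by non-parametric bootstrap from control replicates, models
    it with a Gaussian GLM on log mean volume and gel position to obtain
    spot-specific significance thresholds, and calls differential expression
    by the conjunction of an FDR-adjusted Welch t-test and the threshold
    criterion. Includes reference-line validation, noncentral-t and exact
    Welch power analysis for pilot sample-size planning, spectral-count /
    NSAF deconvolution of mixed protein spots with Western-blot triage, a
    synthetic spot-volume and MS hit-list generator for validation, and a
    command-line interface over the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
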