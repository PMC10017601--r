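Package: fcdscore
Title: Facial Canal Dehiscence Imaging Score and Diagnostic Accuracy Analysis
Version: 0.1.0
Authors@R:
    person("fcdscore", "maintainers", email = "fcdscore@example.org",
           role = c("aut", "cre"))
Description: Tools for an ordinal imaging scoring method that identifies
    facial canal dehiscence (FCD) of the tympanic segment on
    ultra-high-resolution CT. Implements the per-wall 0-3 appearance score,
    the composite FCD score (lateral + inferior wall) with its strict
    "< cutoff" classification rule, Cohen's kappa inter-observer agreement
    with asymptotic confidence intervals, the Freeman-Halton (Fisher) exact
    test for r x c score tables via margin-constrained enumeration, ROC/AUC
    analysis for ordinal scores with tie correction, Youden-index cutoff
    selection, predictive values, reconstruction of per-group score
    distributions from published per-cutoff classification rates, and a
    synthetic-cohort generator with closed-form agreement and AUC oracles
    for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
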