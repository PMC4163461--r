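Package: hbfin
Title: Hierarchical Bayesian Fuzzy Inference Nets for Hemodynamic Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for rule-based cardiovascular diagnosis from sphygmogram-derived
    hemodynamic parameters. Derives stroke volume, arterial compliance and peripheral
    resistance from pulse-wave morphological features via an elastic-cavity model;
    encodes condition bands that classify symptom values as pathological-high (a),
    pathological-low (b) or normal (c); parses universally quantified function formulas
    in a predicate-logic dialect and assembles them into staged Bayesian inference nets;
    quantifies evidence nodes with fuzzy membership grades fitted from labeled cohorts
    (polynomial, sigmoid or quasi-Gaussian families) converted to likelihood-of-
    sufficiency and likelihood-of-necessity multipliers; and propagates odds-likelihood
    updates stage by stage with piecewise-linear interpolation for uncertain evidence
    and a full explanation trace. Includes a synthetic cohort generator and an
    evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    yaml,
    jsonlite,
    igraph,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
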