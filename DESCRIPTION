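Package: interadd
Title: Additive Interaction Analysis for Matched Case-Control Studies
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the case-control epidemiology of additive
    (biologic) interaction between two binary exposures. Builds 2x2 and
    2x2x2 contingency tables from subject-level records, estimates crude
    odds ratios with Woolf confidence intervals and Haldane-Anscombe
    zero-cell correction, fits unconditional logistic regression by
    iteratively reweighted least squares, and computes the additive
    interaction measures RERI (relative excess risk due to interaction),
    the synergy index SI, the attributable proportion AP, and the
    pure-factor attributable proportion PAP, with delta-method and
    bootstrap interval estimation. Includes a seeded generator of 1:1
    matched case-control cohorts with known stratum odds ratios (hence
    known true interaction measures) so every stage can be validated
    against ground truth, and packaged contingency-table fixtures from a
    published hypertension case-control study of family history and
    diabetes/lifestyle exposures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
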