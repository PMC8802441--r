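Package: injurypheno
Title: Data-Driven Dissection of Injury Events in Matched Case-Control
    Health Administrative Data
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for screening thousands of binary ICD-10 diagnosis codes
    against case status in 1:1 matched case-control cohorts and for
    assembling the retained codes into interpretable injury-event
    phenotypes.  The pipeline covers event-window detection around an index
    date, code binarization, matched McNemar screening with
    Benjamini-Yekutieli false discovery rate control, factor construction by
    the principal-components method with a loading cutoff, Haddon Matrix
    (host/agent/environment) designation, conditional logistic regression
    for matched pairs, Fisher-z tests for sex differences in factor
    correlation structure, and Ward-linkage clustering of factors on
    correlation-based distance.  A synthetic matched-cohort generator with
    planted ground truth (latent factor blocks, case-vs-reference odds
    ratios, sex-specific correlations) makes every stage testable without
    access-restricted health records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
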