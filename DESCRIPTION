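Package: fuzzfuse
Title: Fuzzy-Rank Decision Fusion for Classifier Ensembles
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision-level fusion of classifier confidence scores using a
    re-parameterized Mitscherlich rank transform. Given per-class softmax
    confidence matrices from several base classifiers, computes fuzzy ranks,
    penalized fuzzy rank sums and complemented confidence sums restricted to
    each classifier's top-k classes, and fuses them into a final argmin
    decision. Includes the classical fusion baselines (maximum probability,
    average probability, sum rule, majority voting, accuracy-weighted
    average), confusion-matrix evaluation with macro-averaged metrics,
    one-vs-rest ROC-AUC, McNemar's paired test, a seeded synthetic generator
    of realistic softmax score banks, and CSV/JSON file interfaces with a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
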