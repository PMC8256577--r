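Package: fishlink
Title: Probabilistic Record Linkage for Commercial Fishing Injury Surveillance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links de-identified commercial fishing injury and fatality
    datasets with probabilistic record linkage in the Fellegi-Sunter
    tradition. Provides a harmonized incident/person record schema, a
    synthetic-universe generator with planted ground truth emulating four
    Pacific Northwest surveillance datasets, full-index pair comparison with
    tolerance-based field agreement, golden-dataset construction from
    verified candidates and scrambled non-matches, four linkage classifiers
    (supervised naive Bayes, unsupervised expectation/conditional
    maximization, ridge-penalized logistic regression, and a linear support
    vector machine), threshold classification, linkage quality metrics
    (precision, recall, f-score), and study-level match accounting for
    duplicates, close matches, and multi-dataset overlaps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
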