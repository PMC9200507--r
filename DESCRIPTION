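Package: mmaselect
Title: Memory-Based Metaheuristic Attribute Selection for Clinical Risk Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Wrapper feature selection for tabular clinical risk data using a
    memory-buffer (tabu-style) local search over feature subsets, combined with
    K-means outlier filtering and a mixed Gaussian/categorical Naive Bayes
    classifier evaluated by stratified 10-fold cross-validation. Includes the
    full preprocessing chain (mean/mode imputation, min-max normalization),
    a confusion-matrix metric suite with Matthews correlation coefficient,
    per-attribute 0-10 relevance scoring across search restarts, baseline
    selection heuristics (greedy stepwise, best-first, genetic, binary PSO)
    sharing the same fitness, and a synthetic clinical-table generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
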