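Package: statescape
Title: Gene Expression State-Transition Analysis via Reference-Anchored
    PCA and Pareto Tail Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Characterizes transitions between two biological states
    (normal vs. disease, ancestral vs. evolved) from bulk expression
    matrices. Differential expressions are measured against a
    geometric-mean reference profile built from the initial-state
    samples, principal components are extracted from the
    reference-anchored second-moment matrix of log2 fold variations,
    and the over-/under-expression tails of the cumulative
    differential-expression distribution are summarized by Pareto
    exponents. Transitions are classified as continuous or
    discontinuous from the fraction of differentially expressed genes.
    Includes a synthetic two-state data generator with planted
    Pareto-tailed fold changes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
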