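Package: burnoutGMDH
Title: Self-Organizing GMDH Polynomial Networks for Job-Burnout Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the Group Method of Data Handling (GMDH)
    self-organizing polynomial neural network for binary classification of
    job burnout from demographic, COVID-19 stress, resilience, and Maslach
    Burnout Inventory scale scores. Partial descriptions (quadratic
    two-input neurons) are fitted by least squares, selected by an external
    validation criterion, and stacked layer by layer until the criterion
    stops improving; the raw features reachable from the output neuron form
    an automatic feature-selection readout. Also provides a Gaussian-copula
    synthetic survey-cohort generator calibrated to published demographic
    marginals, scale means, and Pearson correlation structure, plus data
    splitting, confusion-matrix evaluation, k-fold cross-validation, and
    reproducible CSV/JSON/YAML pipeline tooling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
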