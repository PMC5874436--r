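Package: nonadh
Title: Topic-Model Detection of Medication Noncompliance in Patient Forum Posts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for detecting forum posts that describe
    medication noncompliance (self-decided dose changes and treatment
    cessation). Provides French-oriented text preprocessing with dosage-mention
    standardization, document-term matrix construction with sparsity-scan
    vocabulary selection and TF-IDF weighting, latent Dirichlet allocation
    fitted by maximum a posteriori EM with log-Bayes-factor selection of the
    number of topics, message-topic assignment by a token-fraction threshold,
    extraction of messages flagged by noncompliance topics, the associated
    evaluation arithmetic (precision, recall, Cohen kappa, review sampling),
    and a synthetic forum-corpus generator with planted noncompliance topics
    for download-free benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
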