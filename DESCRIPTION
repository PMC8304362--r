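Package: rine
Title: Redundant Information Neural Estimation for Partial Information
    Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimates the redundant information that multiple sources carry
    about a discrete target by jointly training per-source probabilistic
    decoders whose predictive distributions are constrained to agree, with a
    reverse-annealed Lagrange coefficient on the agreement penalty. Includes
    exact machinery for finite joint distributions: canonical partial
    information decomposition benchmark tasks, plug-in entropy and mutual
    information, the Gacs-Korner common-variable redundancy oracle, seeded
    sampling of datasets from probability tables, and a synthetic class-overlap
    task for comparing redundancy against cosine similarity under noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
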