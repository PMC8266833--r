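Package: polysim
Title: Stochastic Simulation of Template-Based Polymerization Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An exact stochastic simulator for sequence-based cellular
    processes such as replication, transcription and translation. Freely
    diffusing chemicals are represented as population pools while
    sequence-bound molecules (polymerases, ribosomes) are tracked as
    lightweight particles carrying a template reference and a reading
    position. Six reaction classes (chemical reaction, sequence binding,
    translocation, loading, release, and annotation-triggered switches)
    are simulated with Gillespie's stochastic simulation algorithm using
    one of three interchangeable reaction-selection structures: the direct
    method, a binary partial-sum tree, and a constant-time
    composition-rejection scheme. The package includes a plain-text model
    dialect with parser and writer, programmatic builders for benchmark
    and case-study models (linear conversion cascades, synthetic-genome
    gene expression at three granularities, tetracycline inhibition of
    translation, T-box transcription attenuation), and analytic validation
    oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
SystemRequirements: C++17
Config/testthat/edition: 3
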