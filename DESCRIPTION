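Package: fieldrank
Title: Field-Specific Article Importance in Citation Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds per-field and field-pair directed citation networks from
    DOI-to-DOI citation dumps and subject-heading annotations, generates
    degree-preserving null ensembles of each field-pair network with the
    directed three-edge swap, converts article PageRanks into permutation
    percentiles against the ensemble, and derives field-specific article
    affinity and journal-ranking tables. Includes a synthetic corpus
    generator with preferential attachment, cross-field citations, and
    planted field-favored articles so the whole pipeline can be exercised
    end to end without external data.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
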