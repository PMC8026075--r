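Package: binsimco
Title: Base-Rate Effects on the Concordance of Binary Similarity Coefficients
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how attribute base rates affect the agreement
    among binary similarity coefficients. Provides a registry of 71 similarity
    coefficients defined on the 2x2 contingency quadruple (a, b, c, d) of two
    binary attributes, a Monte-Carlo generator of quadruples under controlled
    base-rate pairs, K-median (p-median) partitioning of inter-coefficient
    correlation matrices by a multistart fast-interchange heuristic, and
    Hubert-Arabie adjusted-Rand comparison of the resulting partitions,
    including co-membership stability analysis across base-rate conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
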