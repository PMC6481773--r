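Package: ewdms
Title: Edge-Weighted Dense Module Search Integrating GWAS and Differential
    Co-Expression Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies disease-associated gene modules by greedy
    edge-weighted dense module searching over a protein-protein interaction
    network, combining gene-level GWAS association signals (node weights)
    with two-condition differential co-expression (edge weights). Includes
    permutation-based module significance, iterative merging of redundant
    modules into mega-modules, hub-gene identification by connectivity and
    eigencentrality, cross-GWAS validation by permutation overrepresentation
    and score regression, hypergeometric over-representation analysis, and a
    synthetic-data generator with planted modules for end-to-end calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
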