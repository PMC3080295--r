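Package: iknn
Title: Integrated k-Nearest-Neighbour Discovery of Gene Biosignatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Retrieves query-driven gene neighbourhoods by fusing Gene
    Ontology functional similarity (Lin's information-content measure with
    maximum inter-set aggregation) and absolute gene co-expression into a
    single ranking score, and evaluates the resulting biosignatures as
    two-condition classifiers using linear support vector machines under
    leave-one-out cross-validation. Includes readers for expression
    matrices, OBO ontologies, GAF annotation files and edge lists, a
    SAM-style moderated difference statistic with permutation-based false
    discovery rate estimation for data-driven query selection, and a
    seeded generator of synthetic two-condition cohorts with planted
    co-expressed, functionally coherent, treatment-responsive gene
    modules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
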