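Package: dcpred
Title: Drug Cocktail Network Analysis and Drug Combination Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a drug cocktail network from tables of effective drug
    combinations, computes therapeutic similarity between drugs from their
    Anatomical Therapeutic Chemical (ATC) codes, characterises the network's
    topology (degree distribution, power-law fit, components, star and hub
    drugs), tests therapeutic-similarity assortativity against a
    degree-preserving rewiring null model, and ranks candidate drug pairs
    with a shared-neighbour hypergeometric statistic (the DCPred family of
    models). Includes ROC-based evaluation of rankings, target-protein
    proximity analysis on a scored protein-protein interaction network, and
    deterministic synthetic-data generators so the full pipeline can be
    exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    Matrix,
    stats,
    utils,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
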