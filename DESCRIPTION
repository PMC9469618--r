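Package: crsnet
Title: Network Prioritization of CRS-Associated Cytokines with a
    Meta-Learned Graph Convolutional Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes cytokines associated with cytokine release syndrome
    (CRS) in CAR-T therapy from a protein-protein interaction network. A
    two-layer graph convolutional classifier, initialized by first-order
    episodic meta-learning, is trained under a positive-unlabeled protocol:
    known CRS cytokines are the positives, reliable negatives are selected
    and iteratively relabeled to convergence, and a multi-restart ensemble
    median scores every node. Downstream, candidate sets are tested for
    gene-set enrichment (hypergeometric test with Benjamini-Hochberg FDR)
    and enriched pathways are screened for crosstalk via Jaccard and overlap
    coefficients with a multi-step filter cascade. A synthetic-data module
    generates planted-community interaction graphs and overlapping pathway
    collections so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
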