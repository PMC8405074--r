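Package: netmark
Title: Consensus Network Biomarker Discovery from Expression and Interaction Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-cycle consensus biomarker-discovery pipeline for paired
    tumor and peripheral-blood expression studies. The first cycle scores a
    cancer-signature protein-protein interaction network topologically
    (degree, betweenness centrality, power-law goodness of fit) and selects
    central genes as the union of hubs and high-betweenness nodes. The
    second cycle calls differentially expressed genes in each compartment
    (Welch t-test, Benjamini-Hochberg adjustment, joint absolute-logFC and
    adjusted-P filter), intersects them across compartments with direction
    agreement, and intersects the shared set with the central genes to
    yield consensus biomarkers. Downstream characterization includes
    mutual-information co-expression network inference with data-processing-
    inequality pruning and seed-gene module extraction, Fisher-exact gene-set
    enrichment against GMT libraries, Kaplan-Meier survival stratification
    with log-rank comparison and observed/expected hazard ratios, and
    comparative delta-delta-Ct qPCR quantification with Kruskal-Wallis
    testing. A seeded synthetic-data generator with planted ground truth
    drives the full pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    survival,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
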