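Package: ceRNAstage
Title: Stage-Resolved Competing Endogenous RNA Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs and analyses stage-resolved competing endogenous RNA
    (ceRNA) networks from lncRNA, microRNA and mRNA expression profiles with
    clinical stage and survival annotations. Provides differential-expression
    filtering against normal tissue, microRNA-target matching through curated
    interaction tables with negative-correlation selection, assembly of one
    doubly bipartite lncRNA-microRNA-mRNA network per tumour stage,
    partitioning into a common network (CCEN) shared by all stages and
    stage-unique networks (UCENs), hypergeometric over-representation tests
    with an enrichment-efficiency statistic, and Kaplan-Meier/log-rank
    screening of microRNAs for pan-stage and stage-specific prognostic value.
    A seeded synthetic-data generator with a ground-truth ledger supports
    calibration and recovery testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
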