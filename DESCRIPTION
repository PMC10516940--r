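Package: icasort
Title: In Silico Models of Image-Activated Cell Sorting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale models of a real-time image-activated cell sorter:
    synthetic class-conditional classifier scores and embeddings stand in for a
    trained convolutional network, and the package implements in silico
    rare-cell mixture evaluation (confusion matrices, ROC curves, and
    precision-recall curves reweighted to extreme target proportions), an
    event-driven Poisson simulation of pneumatic-valve sorting with coincidence
    capture, dead time and arrival-prediction jitter, SNP-panel allele-fraction
    estimation of sorted-pool purity and fold enrichment by binomial maximum
    likelihood, and an embedding-based semi-supervised annotation workflow with
    agglomerative clustering, metadata label constraints, inter-labeler quality
    control and hard-example mining.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mclust,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
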