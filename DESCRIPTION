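Package: iwhmb
Title: Network-Weighted Individualized Pathway Mutation Burden Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores somatic mutation profiles at the pathway level by
    weighting each mutated gene with its normalized network centralities
    (degree, betweenness, eigenvector) inside per-gene-set subnetworks of a
    cohort-specific protein-protein interaction network, then standardizes
    the weighted burden within each sample to remove the global tumor
    mutational burden confound. Downstream tools cluster the resulting
    score matrix into pathway-mutation subtypes (including a subsampling
    consensus clustering), link scores to gene expression by per-gene
    support-vector regression with a linear kernel, build positive
    co-expression networks and module eigengenes, and prioritize bridge
    hub genes by random walk with restart over an integrated interaction
    network. A synthetic cohort generator with planted subtypes, planted
    expression responses and planted bridge genes makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
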