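Package: ceRNAfunnel
Title: Funnel-Style Discovery of circRNA-miRNA-mRNA Feed-Forward Loops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds competing endogenous RNA (ceRNA) networks from validated
    miRNA-target interactions and circRNA sponge tables, following a
    funnel-style candidate selection: miRNAs targeting a gene signature,
    circRNAs sponging those miRNAs filtered by miRNA-binding-site counts
    against the cohort median, and enumeration of feed-forward-loop motifs in
    which a circRNA sponges a miRNA that targets the circRNA's own host gene.
    Includes an RNA-binding-protein enrichment screen, a self-contained
    nonparametric test kernel (Mann-Whitney, Kruskal-Wallis with Dunn
    post-hoc, Fisher exact, tie-aware Spearman, fold-change between medians),
    an expression-association battery for clinically annotated cohorts, qPCR
    delta-Ct utilities, and seeded synthetic-data generators with planted
    ground truth for offline validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    methods,
    stats,
    SummarizedExperiment,
    S4Vectors,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
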