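Package: netarch
Title: Rich-Club, Knotty-Centre and Module Architecture of Disease
    Interactomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Graph-theoretic characterization of literature-curated
    protein-protein interaction networks. Provides global topology metrics
    (path length, clustering, efficiency, degree power-law fit),
    degree-preserving null ensembles and the small-world index, normalized
    rich-club detection with regime calling and one-sample t-test
    significance, a node centrality battery with brokering coefficients and
    multi-sigma central-core extraction, knotty-centre (connective core)
    search by greedy hill-climbing or exhaustive enumeration, MCODE-style
    module detection with supernode collapse, targeted triad-removal
    perturbation experiments, local gene-set over-representation analysis,
    and synthetic network generators with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    fgsea,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
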