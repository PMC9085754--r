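Package: regaxis
Title: Drug-Response Classification and lncRNA Regulatory-Axis Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pan-cancer multi-drug-resistance inference chain: classifies cell
    lines or tissue samples as drug-sensitive or drug-resistant from
    log-normalized IC50 matrices, performs Welch-test differential expression
    with double filtration (p-value and log2 fold-change) and cross-drug
    intersection of differentially expressed genes, builds and analyses
    co-expression and protein-protein interaction networks (degree-based hub
    detection, modularity communities, hub intersection), analyses directed
    lncRNA-transcription-factor-gene regulatory networks (out-degree and
    betweenness master-regulator ranking, two-hop indirect regulation,
    feedback-loop detection, cis/trans classification, interaction-site region
    annotation), and runs hypergeometric gene-set enrichment. A synthetic-data
    generator with planted structure makes every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
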