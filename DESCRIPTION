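Package: mirModNet
Title: miRNA-mRNA Correlation-Network Module Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies miRNA-mRNA module pairs from paired expression
    profiles of tumour sample cohorts. Correlations between every miRNA and
    every mRNA are estimated by subsample-averaged Pearson coefficients,
    discretized into a signed bipartite network keeping the top quantile of
    positive and negative correlations, condensed against a cancer-miRNA
    whitelist, and clustered (Manhattan distance, Ward linkage) to extract
    module pairs in which every member has at least two within-module
    connections. Companion tools characterize Fisher z-transformed
    correlation matrices by singular value decomposition with a shuffle
    null, test seed-motif target-site enrichment of modular gene lists with
    Fisher's exact test, run gene-set over-representation with
    Benjamini-Hochberg control, and generate fully synthetic study data
    (expression, 3'UTR and mature miRNA sequences, annotation tables) with
    planted module and motif structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    withr,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
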