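Package: netrepurpose
Title: Network-Based Drug Repurposing via Module Proximity and GO Semantic Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for network-based drug repurposing in complex disease.
    Builds tissue-specific background networks by integrating thresholded
    transcription-factor regulatory circuits with expression-filtered
    protein-protein interactions, assembles disease gene lists from GWAS
    and text-mining sources with an over-representation filter, detects
    disease modules with random-walk (walktrap) community detection,
    constructs network drug modules from drug targets and perturbation
    signatures filtered by Wang-method GO semantic similarity, and scores
    drug-disease module proximity by combining a diameter-normalized
    closest network distance with Best-Match-Average semantic similarity.
    Significance is assessed against a degree-binned, distance-preserving
    randomization null. Includes a seeded synthetic-data generator that
    emits every input format with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
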