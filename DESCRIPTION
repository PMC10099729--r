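Package: splicentropy
Title: Splicing Complexity Analysis on Contiguous Splice Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies alternative-splicing complexity from transcript
    annotations and splice-junction read counts. Collapses transcripts into
    non-overlapping exonic nodes, builds contiguous splice graphs, enumerates
    local isoform paths per event, and estimates path abundances by
    expectation-maximization to obtain percent-spliced-in (PSI), Shannon
    splicing entropy and discrete complexity bins. Downstream modules classify
    events across tissues, infer the evolutionary age of alternative splicing
    by single-change parsimony on a rooted species tree, call developmentally
    regulated events from stage series with a Beta posterior on delta-PSI,
    relate entropy to gene features (tau tissue specificity, rank-sum
    comparisons), benchmark sequence-feature regressors of mean entropy, and
    simulate annotations, abundances, reads, evolutionary histories and stage
    series with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    IRanges,
    Biostrings,
    xgboost
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
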