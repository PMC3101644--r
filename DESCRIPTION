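Package: supertreeq
Title: Quartet-Based Supertree Construction and Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building and benchmarking supertree methods.
    Encodes source trees as weighted quartet sets (all induced quartets,
    or diameter-based random sampling plus topologically-short quartets),
    amalgamates them with a max-cut style divide-and-conquer heuristic,
    and provides the matrix-representation-with-parsimony pathway
    (partial binary encoding, parsimony ratchet, greedy consensus).
    Includes a supertree-profile simulator (pure-birth model trees, gene
    birth-death presence patterns, GTR+Gamma+I sequence evolution,
    clade-based and scaffold datasets at controlled scaffold density), a
    distance-based source-tree estimator, and an evaluation layer with
    false-negative/false-positive/Robinson-Foulds error rates,
    sum-distances to source trees, and rank-correlation summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    phangorn (>= 2.10),
    phytools,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
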