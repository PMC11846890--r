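Package: senesig
Title: Discovery and Scoring of Cell-Type-Specific Cellular Senescence Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers cell-type-specific transcriptomic signatures of cellular
    senescence from age-annotated single-cell UMI count data and scores single
    cells and spatial spots for senescence burden. Candidate genes are ranked by
    a piecewise gene age-dynamic score on positivity proportions with a
    permutation null, assembled into co-positivity networks thresholded by
    per-pair permutation, and clustered into weighted gene hubs. Hubs are
    compared by weighted cosine similarity and hypergeometric overlap, merged
    into universal panels via a Poisson-binomial generating function, and used
    to score cells against expression-bin-matched background genes, with
    outlier calling at three standard deviations and inverse-distance Moran's I
    for spatial clustering of senescent spots. Includes a seeded synthetic-data
    generator emulating age-stratified populations with minority senescent
    subpopulations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    igraph,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
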