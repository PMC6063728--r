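Package: dropscreen
Title: Simulation and Analysis of Pooled CRISPR Dropout Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of pooled CRISPR knockout fitness screens in
    cultured cells: demultiplexing of barcoded amplicon reads into guide
    count tables, low-count filtering and normalization, per-guide log2
    fold-changes, gene-level effect estimates standardized against a
    negative-control permutation null, expression-anchored empirical
    false-discovery rates with hit calling and screen-quality metrics,
    sgRNA candidate enumeration and ranking with a hypergeometric
    nucleotide position matrix learned from screen outcomes, and
    cross-species comparisons of gene essentiality including paralog
    buffering, dependency counts, and copy-number bias.  A seeded
    generator of synthetic screens with realistic passaging bottlenecks,
    guide-efficiency sequence effects, and companion expression,
    orthology, and copy-number tables makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
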