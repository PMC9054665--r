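Package: promotif
Title: Promoter Motif Scanning and Gene-Set Enrichment in TSS-Anchored Windows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scans exact DNA motifs (GC-box, GA-box and related Sp1/Sp4-family
    binding sites) bidirectionally across promoter sequences in a transcription
    start site (TSS)-anchored coordinate frame, summarises per-gene motif counts
    and GC content in configurable promoter windows, and tests whether
    motif-containing genes are over-represented in user-supplied gene sets with
    upper-tail cumulative hypergeometric probabilities and Benjamini-Hochberg
    false discovery rate correction. Also provides permutation tests on per-gene
    motif counts, Welch's t and one-way ANOVA comparisons of GC content between
    gene groups, positional motif-frequency profiles with sliding windows, and a
    synthetic promoter-universe generator with planted motif occurrences for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
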