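Package: dicodon
Title: Dicodon Statistics and tRNA-Pair Enrichment Analysis for Coding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for selecting tRNA isoacceptor pairs that report on the
    synthesis of a specific protein. Assigns a decoding tRNA isoacceptor to
    every sense codon under configurable wobble rules, estimates unordered
    isoacceptor-pair frequencies from overlapping dicodons in a protein of
    interest and in a pooled background transcriptome, and computes enrichment
    factors (E-factors) used to rank candidate fluorescent tRNA pairs and
    negative-control pairs. Includes relative codon-usage comparison between
    sequence sets, a transcriptome-wide leading-pair survey, and a seeded
    synthetic coding-sequence generator with constructive dicodon spiking for
    parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
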