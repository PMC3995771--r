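Package: ampliscan
Title: Degenerate Primer Design and In Silico Amplicon Evaluation for
    SSU rRNA Reference Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs broad-taxonomic-range degenerate PCR primers from a
    taxonomically annotated multiple sequence alignment and evaluates
    candidate primer pairs in silico. Implements a maximum-coverage search
    for IUPAC degenerate oligomers of fixed length and bounded degeneracy
    over alignment windows, primer arithmetic (degeneracy, expansion,
    reverse complement, GC and melting-temperature ranges), ambiguity-aware
    binding-site search and per-taxon coverage tabulation, error-free
    amplicon read simulation for single- and paired-end layouts with
    overlap merging, a leave-self-out best-hit taxonomic assignment
    benchmark with log-e-value combination for read pairs, a gap-aware
    full-length sequence distance, and a synthetic generator of SILVA-like
    aligned reference databases with known taxonomy and planted primer
    sites.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
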