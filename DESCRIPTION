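Package: pseudoscan
Title: Reference-Anchored Detection of Coding-Sequence Disruptions and
    Relative-Rate Tests for Pseudogene Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying gene loss in orthologous coding-sequence
    alignments. Detects and classifies per-allele lesions against a
    designated functional reference (premature stop codons, frameshift and
    in-frame indels, loss of conserved sequence motifs such as the CC
    chemokine cysteine pair, start-codon loss), maps between alignment
    columns and reference nucleotide or codon numbering, scans introns for
    alternative splice-acceptor sites and predicts the resulting
    intron-retention insertions, and implements Tajima's relative-rate test
    from aligned sequence triples or precomputed unique-difference counts.
    A seeded sequence-evolution simulator plants disruption events on a
    phylogeny with post-loss rate acceleration and emits an exact truth
    ledger, so detection and rate-test behaviour can be validated by
    parameter recovery without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
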