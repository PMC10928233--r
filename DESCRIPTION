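Package: mmrdkit
Title: Mismatch Repair Deficiency Read-Outs from Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies mismatch repair deficiency (MMRD) from
    sequencing-derived inputs. Implements a genome-wide
    microsatellite-instability ("MMRDness") score from 1-bp deletions at
    mononucleotide microsatellites (10-15 bp) in low-pass whole-genome
    alignments; Promega-style five-locus panel MSI classification from
    fragment-analysis peak profiles; tumor mutation burden from the
    consensus of two or more somatic variant callers, with hypermutator
    calling; and non-negative least-squares refitting of 96-channel
    trinucleotide mutation catalogs against a signature reference matrix.
    A synthetic-data generator produces every pipeline input (reference
    sequences with embedded microsatellites, slippage reads, multi-caller
    variant sets, signature-mixture catalogs, panel peak profiles) with
    machine-readable ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rsamtools,
    S4Vectors,
    graphics,
    jsonlite,
    methods,
    pracma,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
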