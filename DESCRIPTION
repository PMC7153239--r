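Package: rrftools
Title: Discovery, Filtering and Differential Abundance of rRNA-Derived Fragments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for profiling ribosomal-RNA-derived
    fragments (rRFs) in short RNA-seq data. Reads are adapter- and
    quality-trimmed, mapped exhaustively and exactly onto flank-padded
    reference rRNAs (keeping fragments that straddle an rRNA terminus),
    and filtered through three tiers: a per-sample adaptive raw-count
    threshold, a reads-per-million abundance floor, and per-rRNA minimum
    fragment lengths derived from a genomic signal-to-noise criterion
    computed against the "rRNA space" (full-length rRNA loci, annotated
    rRNA repeats, and partial rRNA copies found by a built-in
    seed-and-extend local aligner). Retained fragments are classified by
    position (5', internal, 3', terminus-straddling), labelled with
    reversible sequence-derived "license plates", and tested for sex- and
    population-specific differential abundance with a SAM-style
    permutation test and PLS-DA VIP scoring, intersected into iDARs. A
    synthetic mini-genome and cohort generator with ground-truth
    manifests makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    mixOmics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse
Config/testthat/edition: 3
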