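Package: diplophylo
Title: Phylogenomic Supermatrix Curation, Ancestral States and Topology
    Tests for Millipede Transcriptome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building optimized amino-acid supermatrices from
    per-locus transcriptome ortholog alignments and for downstream
    ordinal-level phylogenetic analyses of millipedes (Diplopoda).
    Implements paired-end FASTQ quality trimming with pair
    resynchronization; per-locus alignment curation (leading-ambiguity
    masking, consensus-divergence paralog removal, uninformative-column
    deletion, length and taxon-occupancy filters, representative-sequence
    selection); conserved-block selection at classic Gblocks parameter
    settings and Monte-Carlo sliding-window masking of low-signal columns;
    concatenation into a partitioned supermatrix with full gap, missing
    data, occupancy and transcriptome-coverage statistics; Fitch parsimony
    ancestral-state reconstruction of discrete unordered characters with
    exhaustive most-parsimonious-reconstruction enumeration; an amino-acid
    pruning likelihood engine (WAG exchangeabilities, discrete-gamma
    rates, per-branch length optimization) producing site-wise
    log-likelihoods; and the CONSEL-style topology test battery (AU, NP,
    BP, PP, KH, SH, WKH, WSH) via multiscale RELL bootstrap. A synthetic
    ortholog-set generator with labeled defects supports end-to-end
    validation of the curation cascade.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    phangorn,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    Matrix,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
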