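Package: unisetr
Title: Comparison and Reconciliation of Multiple De Novo Transcriptome Unigene Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating and reconciling several independently built
    transcriptome unigene sets (for example long-read consensus transcripts
    versus short-read or hybrid assemblies) for the same organism. Provides a
    seeded synthetic-study generator with a machine-readable truth ledger,
    contig summary statistics (N50, GC content), TPM normalisation, an
    expression-threshold convergence scan, deterministic six-frame ORF
    calling, k-mer anchored detection of shared sequence blocks, greedy
    redundancy collapse with CD-HIT-EST semantics, cross-set homology grouping
    with structural classification of members (UTR-end extensions,
    set-exclusive isoforms, concatenated and chimeric assemblies), and
    agglomerative expression clustering with WPGMA (McQuitty) and complete
    linkage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Matrix,
    methods,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
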