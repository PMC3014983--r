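Package: ContigGraphKit
Title: Post-Assembly Clustering, Variant Screens and Sex-Specific Calling
    for Pooled De Novo Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the post-assembly stage of pooled, sex-labelled de
    novo transcriptome projects. Builds split-read contig graphs and
    classifies their connected components into merged divergent alleles,
    duplicated-gene contig pairs and alternative-splicing structures using
    pairwise sequence identity bands; filters variant calls and computes
    per-contig transition/transversion and Ka/Ks selection screens with
    percentile flagging and length regression; calls sex-specific genes
    from presence/absence of sex-of-origin read classes at an e-value
    ladder, with Fisher exact GO-term enrichment; clusters sequences by
    shared homology hits, counts unique homologues across e-value
    cut-offs, detects chimeric contigs and rescues singletons by alignment
    to contigs. A synthetic-data generator emulates assembler outputs
    (contigs, split reads, variants, homology hits) with a complete
    ground-truth ledger so that every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
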