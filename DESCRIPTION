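Package: fungits
Title: Pruning and Structuring of Fungal ITS2 Illumina Metabarcoding Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A transparent, fully native pipeline for cleaning fungal ITS2
    amplicon data sequenced as dual-tagged paired-end Illumina MiSeq reads.
    Covers mean-quality read filtering, quality-aware paired-end assembly,
    multi-primer artifact removal, 5'-3' reorientation, strict double-label
    demultiplexing, primer/label trimming, anchor-based ITS2 extraction,
    dereplication and greedy centroid OTU clustering at 97% identity with
    de-novo bimera rejection, reference-based chimera filtering, lowest
    common ancestor taxonomy gating of fungal OTUs, and construction of the
    OTU-by-sample abundance table. Every stage emits a pruning report of
    reads kept and discarded. A ground-truthed read simulator generates
    dual-tagged amplicon communities (with configurable sequencing error,
    chimeras, multi-primer artifacts, and tag corruption) so that every
    stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
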