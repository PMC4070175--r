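Package: txConsensus
Title: Consensus De Novo Transcriptome Assembly Evaluation and Merging
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and evaluating de novo transcriptome
    assemblies by consensus. Implements quality trimming of FASTQ reads by
    cumulative error probability, duplicate removal and length filtering
    with per-stage accounting, seeded random subsampling of read pairs,
    assembly evaluation metrics (N50, length statistics, reads mapped back
    to transcripts, core-gene completeness proxy), k-mer selection for
    single k-mer assemblies, redundancy removal by greedy identity
    clustering, and merging of assemblies from multiple tools into
    consensus contigs with provenance tracking and a robust-contig filter.
    A seeded simulator generates ground-truth transcriptomes, paired-end
    reads and corrupted multi-tool assemblies so the whole workflow can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    data.table
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Transcriptomics, Sequencing, Assembly, QualityControl
RoxygenNote: 7.3.3
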