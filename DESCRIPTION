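Package: tssmapr
Title: Differential RNA-Seq Transcription Start Site Mapping for Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide transcription start site (TSS) mapping from paired
    differential RNA-seq (dRNA-seq) 5'-end libraries. Implements a
    position-wise Skellam test contrasting an enriched ("+") library against
    an untreated ("-") control, replicate and condition consolidation with
    rule-based curation, positional classification of TSSs relative to gene
    annotation (primary, internal, antisense, orphan), 5'UTR and leaderless
    mRNA analysis, promoter -10/-35 window construction with a
    one-occurrence-per-sequence EM motif finder, comparison against
    previously published TSSs, and a synthetic-data generator emulating
    GC-rich multi-replicon bacterial genomes with planted TSSs for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
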