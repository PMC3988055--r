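Package: isocurate
Title: Validation, Collapse and Novelty Classification of Spliced Long-Read Transcript Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Curates spliced long-read cDNA alignments into transcript isoform
    models. Each splice junction is validated against the genome for canonical
    GT-AG splice motifs and against a database of orthogonal short-read splice
    junctions; multi-exon alignments passing both checks are collapsed by their
    intron chain ("junction code") into isoform models carrying the furthest
    observed transcription start and end sites. Models are classified against a
    reference annotation into annotated isoforms, novel isoforms of known genes
    and novel gene regions, with bookkeeping of novel exons. Also provides
    any-overlap matrices between feature sets, per-transcript coverage
    profiles, splice-site distance-to-annotation histograms, and a seeded
    simulator of gene models, truncated long reads with donor-shift alignment
    artifacts, and short-read junction evidence with machine-readable ground
    truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
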