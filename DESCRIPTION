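Package: pitkit
Title: Proteomics Informed by Transcriptomics: ORF Databases, Peptide FDR,
    and Genome Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for proteogenomic analysis in which tandem mass spectra
    are searched against sample-specific protein databases built from
    assembled transcripts. Implements six-frame open reading frame (ORF)
    database construction from transcript FASTA, target-decoy peptide-level
    false discovery rate estimation with q-values, protein ambiguity grouping
    with anchor proteins and a two-peptide rule, projection of identified
    peptides through spliced transcript-to-genome alignments into GFF3, SAM
    and tabular genome annotation, homology-aware comparison of
    identification lists obtained from different search databases, and a
    deterministic synthetic-data generator (genomes, spliced gene models,
    transcripts, scored target/decoy peptide-spectrum matches) with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    GenomicRanges,
    Rsamtools,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
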