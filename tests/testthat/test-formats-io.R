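test_that("FASTA parsing concatenates multi-line records and keeps order", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">t1 demo", "ATG", "CCC", ">t2", "GGGG"), f)
  recs <- read_fasta(f)
  expect_equal(recs$id, c("t1", "t2"))
  expect_equal(recs$description, c("demo", ""))
  expect_equal(recs$sequence, c("ATGCCC", "GGGG"))
})

test_that("FASTA dialect violations are named errors", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "AA", ">a", "CC"), f)
  expect_error(read_fasta(f), "duplicate id")
  writeLines(c("ACGT", ">a", "AA"), f)
  expect_error(read_fasta(f), "line 1")
  writeLines(character(), f)
  expect_equal(nrow(read_fasta(f)), 0L)
})

test_that("FASTA write/read round-trips 50 random records and agrees with Biostrings", {
  set.seed(11)
  recs <- fasta_records(
    id = sprintf("seq%02d", 1:50),
    sequence = vapply(sample(5:300, 50, replace = TRUE), random_dna,
                      character(1)),
    description = sample(c("", "some description", "x y z"), 50,
                         replace = TRUE))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(recs, f, width = 60)
  back <- read_fasta(f)
  expect_equal(back, recs)
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(back, f2, width = 60)
  expect_identical(readLines(f), readLines(f2))
  bs <- Biostrings::readBStringSet(f)
  expect_equal(unname(as.character(bs)), recs$sequence)
  expect_equal(sub("\\s.*$", "", names(bs)), recs$id)
})

test_that("PSM tables parse scores and enforce mandatory columns", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("spectrum_id\tpeptide\tscore",
               "s1\tPEPTIDEK\t12.5", "s2\tAAAK\t7"), f)
  psms <- read_psm_table(f)
  expect_equal(psms$score, c(12.5, 7.0))
  expect_equal(psms$modifications, c("", ""))
  writeLines(c("spectrum_id\tscore", "s1\t5"), f)
  expect_error(read_psm_table(f), "peptide")
  writeLines(c("spectrum_id\tpeptide\tscore", "s1\tAAAK\tnot_a_number"), f)
  expect_error(read_psm_table(f), "line")
})

test_that("a generated 1000-row PSM table round-trips", {
  set.seed(5)
  psms <- data.frame(
    spectrum_id = sprintf("scan%04d", 1:1000),
    peptide = replicate(1000, random_protein(sample(7:20, 1))),
    modifications = sample(c("", "Oxidation@3"), 1000, replace = TRUE),
    score = round(rnorm(1000, 20, 5), 4),
    proteins = sample(c("P1", "P1;P2", ""), 1000, replace = TRUE),
    stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_psm_table(psms, f)
  back <- read_psm_table(f)
  expect_equal(nrow(back), 1000L)
  expect_equal(back[, names(psms)], psms)
})

test_that("BLAST outfmt-6 parses numeric fields and rejects short lines", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("q1\ts1\t98.0\t50\t1\t0\t1\t50\t1\t50\t1e-40\t180", f)
  hits <- read_blast_tabular(f)
  expect_equal(hits$evalue, 1e-40)
  expect_equal(hits$bitscore, 180.0)
  expect_equal(hits$query_id, "q1")
  writeLines("q1\ts1\t98.0", f)
  expect_error(read_blast_tabular(f), "line 1")
  writeLines(character(), f)
  expect_equal(nrow(read_blast_tabular(f)), 0L)
})

test_that("100 synthetic BLAST hits round-trip field by field", {
  set.seed(21)
  hits <- do.call(rbind, lapply(1:100, function(i) data.frame(
    query_id = paste0("q", i), subject_id = paste0("s", sample(50, 1)),
    pct_identity = round(runif(1, 30, 100), 2),
    aln_length = sample(20:500, 1), mismatches = sample(0:30, 1),
    gap_opens = sample(0:4, 1), q_start = 1L, q_end = 50L,
    s_start = 3L, s_end = 52L,
    evalue = 10^-round(runif(1, 0, 60), 2),
    bitscore = round(runif(1, 40, 900), 1), extra = "",
    stringsAsFactors = FALSE)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_blast_tabular(hits, f)
  back <- read_blast_tabular(f)
  expect_equal(back$query_id, hits$query_id)
  expect_equal(back$pct_identity, hits$pct_identity)
  expect_equal(back$evalue, hits$evalue, tolerance = 1e-12)
  expect_equal(back$bitscore, hits$bitscore)
})

test_that("GFF3 serialization emits the canonical nine-column line", {
  feats <- gff3_features("chr1", "pitkit", "peptide", 107L, 110L,
                         strand = "+", phase = 0L,
                         attributes = list(c(ID = "pep1")))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(feats, f)
  lines <- readLines(f)
  expect_equal(lines[1], "##gff-version 3")
  expect_equal(lines[2], "chr1\tpitkit\tpeptide\t107\t110\t.\t+\t0\tID=pep1")
  write_gff3(feats[0, ], f)
  expect_equal(readLines(f), "##gff-version 3")
})

test_that("GFF3 write -> read -> write is idempotent on 100 random features", {
  set.seed(31)
  start <- sample(1:10000, 100)
  feats <- gff3_features(
    sample(c("chr1", "chr2"), 100, replace = TRUE), "pitkit",
    sample(c("mRNA", "exon", "CDS", "peptide"), 100, replace = TRUE),
    start, start + sample(0:500, 100, replace = TRUE),
    score = ifelse(runif(100) < 0.5, NA, round(runif(100), 4)),
    strand = sample(c("+", "-", "."), 100, replace = TRUE),
    phase = sample(c(NA, 0L, 1L, 2L), 100, replace = TRUE),
    attributes = lapply(1:100, function(i)
      c(ID = sprintf("f%03d", i), Name = "a;b=c,d e%f")))
  f1 <- withr::local_tempfile(fileext = ".gff3")
  f2 <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(feats, f1)
  back <- read_gff3(f1)
  expect_equal(back$attributes[[1]][["Name"]], "a;b=c,d e%f")
  write_gff3(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("GFF3 output is accepted by an independent parser", {
  skip_if_not_installed("rtracklayer")
  feats <- gff3_features("chr1", "pitkit", c("mRNA", "exon"),
                         c(101L, 101L), c(220L, 110L), strand = "-",
                         attributes = list(c(ID = "m1", Name = "v;1"),
                                           c(ID = "e1", Parent = "m1")))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(feats, f)
  gr <- rtracklayer::import(f, format = "gff3")
  expect_equal(length(gr), 2L)
  expect_equal(GenomicRanges::start(gr), c(101L, 101L))
  expect_equal(GenomicRanges::end(gr), c(220L, 110L))
  expect_equal(gr$ID, c("m1", "e1"))
  expect_equal(gr$Name[1], "v;1")
})

test_that("GFF3 writer refuses invariant violations naming the feature", {
  feats <- gff3_features("chr1", "x", "exon", 5L, 10L,
                         attributes = list(c(ID = "bad1")))
  feats$start <- 20L
  f <- withr::local_tempfile(fileext = ".gff3")
  expect_error(write_gff3(feats, f), "bad1")
})

test_that("SAM emission sets headers, flags, and bounds-checks CIGARs", {
  rec <- sam_records("pep1", 0L, "chr1", 107L, "4M90N5M", "ACGTACGTA")
  expect_equal(cigar_reference_length(rec$cigar), 99L)
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(rec, c(chr1 = 1000L), f)
  lines <- readLines(f)
  expect_true(any(startsWith(lines, "@SQ\tSN:chr1\tLN:1000")))
  rev_rec <- sam_records("pep2", 16L, "chr1", 5L, "9M")
  write_sam(rev_rec, c(chr1 = 1000L), f)
  expect_true(bitwAnd(read_sam(f)$flag, 16L) == 16L)
  expect_error(write_sam(rec, c(chr1 = 100L), f), "pep1")
  expect_error(write_sam(rec, c(chr2 = 1000L), f), "chr1")
})

test_that("SAM output parses identically through Rsamtools", {
  skip_if_not_installed("Rsamtools")
  recs <- sam_records(c("p1", "p2"), c(0L, 16L), c("chr1", "chr2"),
                      c(107L, 11L), c("4M90N5M", "9M"),
                      c("ACGTACGTA", "TTTTTTTTT"))
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(recs, c(chr1 = 1000L, chr2 = 500L), f)
  bam <- Rsamtools::asBam(f, withr::local_tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  aln <- Rsamtools::scanBam(bam)[[1]]
  expect_equal(as.character(aln$qname), c("p1", "p2"))
  expect_equal(aln$pos, c(107L, 11L))
  expect_equal(as.character(aln$cigar), c("4M90N5M", "9M"))
  expect_equal(as.integer(aln$flag), c(0L, 16L))
})

test_that("exon features become strand-aware alignment blocks", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tgmap\texon\t101\t110\t.\t+\t.\tParent=t1",
               "chr1\tgmap\texon\t201\t220\t.\t+\t.\tParent=t1"), f)
  res <- read_transcript_alignments(f)
  aln <- res$alignments[["t1"]]
  expect_equal(unname(aln$blocks),
               matrix(c(0L, 10L, 100L, 110L, 10L, 30L, 200L, 220L),
                      nrow = 2, byrow = TRUE))
  # same exons on minus strand: transcript coordinate 0 maps to genome end 220
  writeLines(c("##gff-version 3",
               "chr1\tgmap\texon\t101\t110\t.\t-\t.\tParent=t1",
               "chr1\tgmap\texon\t201\t220\t.\t-\t.\tParent=t1"), f)
  aln <- read_transcript_alignments(f)$alignments[["t1"]]
  expect_equal(aln$strand, "-")
  expect_equal(unname(aln$blocks[1, ]), c(0L, 20L, 200L, 220L))
  seg <- project_interval(aln, 0L, 1L)
  expect_equal(unname(seg[1, ]), c(219L, 220L))
})

test_that("malformed or inconsistent exon sets are diagnosed, not crashed", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("chr1\tg\texon\t110\t101\t.\t+\t.\tParent=t1"), f)
  expect_error(read_transcript_alignments(f), "coordinates")
  writeLines(c("chr1\tg\texon\t101\t110\t.\t+\t.\tParent=t1",
               "chr2\tg\texon\t201\t220\t.\t+\t.\tParent=t1",
               "chr1\tg\texon\t101\t110\t.\t+\t.\tParent=t2",
               "chr1\tg\texon\t105\t220\t.\t+\t.\tParent=t2",
               "chr1\tg\texon\t101\t110\t.\t+\t.\tParent=t3",
               "chr1\tg\texon\t201\t220\t.\t-\t.\tParent=t3",
               "chr1\tg\texon\t301\t320\t.\t+\t.\tParent=ok1"), f)
  res <- read_transcript_alignments(f)
  expect_equal(sort(res$rejected$transcript_id), c("t1", "t2", "t3"))
  expect_match(res$rejected$reason[res$rejected$transcript_id == "t1"],
               "seqid")
  expect_match(res$rejected$reason[res$rejected$transcript_id == "t2"],
               "overlap")
  expect_named(res$alignments, "ok1")
})

test_that("GTF attribute dialect and Target fallback are accepted", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c('chr1\tg\texon\t101\t110\t.\t+\t.\tgene_id "g1"; transcript_id "tr9";',
               'chr1\tg\texon\t201\t220\t.\t+\t.\tgene_id "g1"; transcript_id "tr9";'), f)
  res <- read_transcript_alignments(f)
  expect_named(res$alignments, "tr9")
  f2 <- withr::local_tempfile(fileext = ".gff3")
  writeLines("chr1\tg\texon\t101\t110\t.\t+\t.\tTarget=tq 1 10", f2)
  expect_named(read_transcript_alignments(f2)$alignments, "tq")
})

test_that("minimal mzIdentML subset is read into PSM records", {
  mzid <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<MzIdentML xmlns="http://psidev.info/psi/pi/mzIdentML/1.1" version="1.1.0">',
    ' <SequenceCollection>',
    '  <Peptide id="pep_1"><PeptideSequence>ELVISLIVESK</PeptideSequence></Peptide>',
    '  <Peptide id="pep_2"><PeptideSequence>AAAAK</PeptideSequence></Peptide>',
    '  <PeptideEvidence id="pe_1" peptide_ref="pep_1" dBSequence_ref="P1" isDecoy="false"/>',
    '  <PeptideEvidence id="pe_2" peptide_ref="pep_2" dBSequence_ref="DECOY_P2" isDecoy="true"/>',
    ' </SequenceCollection>',
    ' <AnalysisData>',
    '  <SpectrumIdentificationList id="sil">',
    '   <SpectrumIdentificationResult id="r1" spectrumID="scan=101">',
    '    <SpectrumIdentificationItem id="i1" peptide_ref="pep_1" rank="1">',
    '     <PeptideEvidenceRef peptideEvidence_ref="pe_1"/>',
    '     <cvParam accession="MS:1002053" name="MS-GF:EValue" value="13.5"/>',
    '    </SpectrumIdentificationItem>',
    '   </SpectrumIdentificationResult>',
    '   <SpectrumIdentificationResult id="r2" spectrumID="scan=102">',
    '    <SpectrumIdentificationItem id="i2" peptide_ref="pep_2" rank="1">',
    '     <PeptideEvidenceRef peptideEvidence_ref="pe_2"/>',
    '     <cvParam accession="MS:1002053" name="MS-GF:EValue" value="7"/>',
    '    </SpectrumIdentificationItem>',
    '   </SpectrumIdentificationResult>',
    '  </SpectrumIdentificationList>',
    ' </AnalysisData>',
    '</MzIdentML>')
  f <- withr::local_tempfile(fileext = ".mzid")
  writeLines(mzid, f)
  psms <- read_mzid(f)
  expect_equal(psms$peptide, c("ELVISLIVESK", "AAAAK"))
  expect_equal(psms$score, c(13.5, 7))
  expect_equal(psms$is_decoy, c(FALSE, TRUE))
  expect_equal(psms$proteins, c("P1", "DECOY_P2"))
})
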