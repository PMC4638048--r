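#' Project a transcript interval onto the genome
#'
#' The transcript interval (0-based half-open) is intersected with each
#' exon block of the spliced alignment and each intersection is mapped
#' affinely to genome coordinates; on strand `-` the transcript axis runs
#' against the genome axis. Junction-spanning intervals yield two or more
#' segments.
#'
#' @param aln A [transcript_alignment()].
#' @param t_start,t_end Transcript interval, 0-based half-open, within the
#'   aligned length.
#' @return Integer matrix with columns `start`, `end` (0-based half-open
#'   genome coordinates), rows ordered by genome coordinate.
#' @export
project_interval <- function(aln, t_start, t_end) {
  len <- aligned_length(aln)
  if (!(t_start >= 0 && t_start < t_end && t_end <= len))
    stop("interval [", t_start, ",", t_end, ") escapes the aligned region ",
         "[0,", len, ") of transcript ", aln$transcript_id)
  b <- aln$blocks
  segs <- list()
  for (i in seq_len(nrow(b))) {
    lo <- max(t_start, b[i, "t_start"])
    hi <- min(t_end, b[i, "t_end"])
    if (lo >= hi) next
    if (aln$strand == "+") {
      g0 <- b[i, "g_start"] + (lo - b[i, "t_start"])
      segs[[length(segs) + 1L]] <- c(g0, g0 + (hi - lo))
    } else {
      g1 <- b[i, "g_end"] - (lo - b[i, "t_start"])
      segs[[length(segs) + 1L]] <- c(g1 - (hi - lo), g1)
    }
  }
  m <- do.call(rbind, segs)
  m <- m[order(m[, 1]), , drop = FALSE]
  colnames(m) <- c("start", "end")
  m
}

#' Project a peptide occurrence onto the genome
#'
#' The peptide's protein offsets are converted to a nucleotide interval on
#' the forward transcript strand (`nt_start + 3*start .. nt_start + 3*end`
#' for forward-frame ORFs; reflected through the ORF's own coordinates for
#' reverse frames) and projected through the spliced alignment. The feature
#' strand combines the alignment strand with the ORF frame sign, and each
#' segment carries a GFF3 phase so that frame-aware consumers can translate
#' the segments in reading order.
#'
#' @param evidence One row of peptide evidence (`peptide`, `start`, `end`,
#'   optionally `peptide_key`; offsets 0-based half-open on the protein).
#' @param orf The matching row of the ORF index (needs `transcript_id`,
#'   `frame`, `nt_start`, `nt_end`).
#' @param aln The transcript's [transcript_alignment()].
#' @return A list of class `genomic_peptide` with `peptide_key`, `peptide`,
#'   `orf_id`, `transcript_id`, `seqid`, `strand`, `segments` (matrix as in
#'   [project_interval()]) and `frame_phase` (integer per segment), or an
#'   object of class `unprojectable_peptide` carrying a `reason` when the
#'   ORF span is not fully inside the aligned region.
#' @export
project_peptide <- function(evidence, orf, aln) {
  if (orf$frame > 0) {
    nt_lo <- orf$nt_start + 3L * evidence$start
    nt_hi <- orf$nt_start + 3L * evidence$end
  } else {
    nt_lo <- orf$nt_end - 3L * evidence$end
    nt_hi <- orf$nt_end - 3L * evidence$start
  }
  len <- aligned_length(aln)
  if (orf$nt_start < 0 || orf$nt_end > len || nt_lo < 0 || nt_hi > len) {
    return(structure(list(reason = sprintf(
      "ORF %s spans [%d,%d) outside aligned region [0,%d) of %s",
      orf$orf_id, orf$nt_start, orf$nt_end, len, aln$transcript_id)),
      class = "unprojectable_peptide"))
  }
  segs <- project_interval(aln, nt_lo, nt_hi)
  # reading strand on the genome: alignment strand flipped by reverse frames
  strand <- if ((aln$strand == "+") == (orf$frame > 0)) "+" else "-"
  reading <- if (strand == "+") seq_len(nrow(segs)) else rev(seq_len(nrow(segs)))
  seg_len <- segs[, "end"] - segs[, "start"]
  before <- cumsum(c(0L, seg_len[reading]))[seq_len(nrow(segs))]
  phase <- integer(nrow(segs))
  phase[reading] <- (3L - before %% 3L) %% 3L
  structure(list(
    peptide_key = if ("peptide_key" %in% names(evidence))
      evidence$peptide_key else evidence$peptide,
    peptide = evidence$peptide, orf_id = orf$orf_id,
    transcript_id = orf$transcript_id, seqid = aln$seqid, strand = strand,
    segments = segs, frame_phase = phase), class = "genomic_peptide")
}

#' SAM position and CIGAR for a projected feature
#'
#' Segments become `M` runs and the gaps between consecutive segments
#' become `N` (intron skip) runs; `pos` is the 1-based leftmost genome
#' coordinate. Reverse-strand features receive flag bit 16.
#'
#' @param segments Segment matrix (0-based half-open, genome-ordered).
#' @param strand `"+"` or `"-"`.
#' @return List with `pos` (1-based), `cigar`, `flag`.
#' @export
to_cigar <- function(segments, strand = "+") {
  segments <- matrix(as.integer(segments), ncol = 2,
                     dimnames = list(NULL, c("start", "end")))
  n <- nrow(segments)
  lens <- segments[, "end"] - segments[, "start"]
  ops <- character(0)
  for (i in seq_len(n)) {
    if (i > 1L) {
      gap <- segments[i, "start"] - segments[i - 1L, "end"]
      if (gap < 0L) stop("segments overlap or are unordered")
      if (gap > 0L) ops <- c(ops, paste0(gap, "N"))
    }
    ops <- c(ops, paste0(lens[i], "M"))
  }
  list(pos = as.integer(segments[1, "start"]) + 1L,
       cigar = paste(ops, collapse = ""),
       flag = if (strand == "-") 16L else 0L)
}

# Splice-aware extraction of a projected feature's coding sequence from the
# genome, in reading order (reverse-complemented for "-" features).
extract_feature_sequence <- function(genome_seq, segments, strand) {
  pieces <- substring(genome_seq, segments[, "start"] + 1L, segments[, "end"])
  fwd <- paste(pieces, collapse = "")
  if (strand == "-") reverse_complement(fwd) else fwd
}

#' Integrate identifications into genome annotation
#'
#' Builds the annotation bundle for everything identified and aligned: one
#' mRNA feature with exon children per aligned transcript, one CDS feature
#' set per identified ORF (an ORF is "identified" when it anchors or
#' belongs to a surviving ambiguity group), and one peptide feature per
#' projected peptide occurrence. Multi-segment (junction-spanning) peptides
#' and CDSs use the GFF3 shared-ID multi-line convention, with `Parent`
#' links peptide -> ORF -> mRNA. Unprojectable items are tallied in the run
#' report, never silently dropped.
#'
#' @param pag_set Surviving ambiguity groups ([group_proteins()]).
#' @param peptides Retained peptide frame with `q_value`
#'   ([filter_peptides()]).
#' @param evidence Peptide-to-protein evidence
#'   ([map_peptides_to_proteins()]).
#' @param orf_index ORF provenance table ([build_orf_database()]).
#' @param alignments Named list of [transcript_alignment()] objects.
#' @param genome Optional genome FASTA record frame; when present, SAM
#'   records carry the spliced coding sequence and reference lengths are
#'   taken from it.
#' @param source GFF3 source tag (default `"pitkit"`).
#' @return List of class `annotation_bundle`: `gff` (feature frame), `sam`
#'   (record frame), `reference_lengths`, `table` (tabular summary),
#'   `features` (list of `genomic_peptide` objects), `report` (counts and
#'   unprojectable diagnostics).
#' @export
integrate_annotations <- function(pag_set, peptides, evidence, orf_index,
                                  alignments, genome = NULL,
                                  source = "pitkit") {
  identified <- unique(c(pag_set$pags$anchor,
                         unlist(pag_set$pags$same_set, use.names = FALSE),
                         unlist(pag_set$pags$sub_members, use.names = FALSE)))
  missing_orf <- setdiff(identified, orf_index$orf_id)
  if (length(missing_orf))
    stop("identified protein(s) absent from the ORF index: ",
         paste(missing_orf, collapse = ", "))
  orfs <- orf_index[orf_index$orf_id %in% identified, , drop = FALSE]
  kept_pep <- unique(unlist(pag_set$pags$peptides, use.names = FALSE))
  ev <- evidence[evidence$protein_id %in% identified &
                   evidence$peptide %in% kept_pep, , drop = FALSE]
  qv <- if (nrow(peptides)) structure(peptides$q_value,
                                      names = peptides$plain_sequence)
        else structure(numeric(), names = character())

  feats <- list(); sams <- list(); tabs <- list(); gfeatures <- list()
  unprojectable <- character()
  used_tr <- intersect(unique(orfs$transcript_id), names(alignments))
  dangling <- setdiff(unique(orfs$transcript_id), names(alignments))

  for (tr in used_tr) {
    aln <- alignments[[tr]]
    b <- aln$blocks
    mrna_id <- paste0("mRNA:", tr)
    feats[[length(feats) + 1L]] <- gff3_features(
      aln$seqid, source, "mRNA", min(b[, "g_start"]) + 1L, max(b[, "g_end"]),
      strand = aln$strand,
      attributes = list(c(ID = mrna_id, Name = tr)))
    go <- order(b[, "g_start"])
    feats[[length(feats) + 1L]] <- gff3_features(
      aln$seqid, source, "exon", b[go, "g_start"] + 1L, b[go, "g_end"],
      strand = aln$strand,
      attributes = lapply(seq_along(go), function(i)
        c(ID = paste0("exon:", tr, ":", i), Parent = mrna_id)))
  }

  pep_serial <- 0L
  for (i in seq_len(nrow(orfs))) {
    orf <- orfs[i, ]
    aln <- alignments[[orf$transcript_id]]
    if (is.null(aln)) next
    len <- aligned_length(aln)
    orf_feature_id <- paste0("orf:", orf$orf_id)
    if (orf$nt_start < 0 || orf$nt_end > len) {
      unprojectable <- c(unprojectable,
                         sprintf("ORF %s outside aligned region of %s",
                                 orf$orf_id, orf$transcript_id))
    } else {
      osegs <- project_interval(aln, orf$nt_start, orf$nt_end)
      ostrand <- if ((aln$strand == "+") == (orf$frame > 0)) "+" else "-"
      reading <- if (ostrand == "+") seq_len(nrow(osegs)) else
        rev(seq_len(nrow(osegs)))
      before <- cumsum(c(0L, (osegs[, "end"] - osegs[, "start"])[reading]))
      phase <- integer(nrow(osegs))
      phase[reading] <- (3L - before[seq_len(nrow(osegs))] %% 3L) %% 3L
      feats[[length(feats) + 1L]] <- gff3_features(
        aln$seqid, source, "CDS", osegs[, "start"] + 1L, osegs[, "end"],
        strand = ostrand, phase = phase,
        attributes = list(c(ID = orf_feature_id,
                            Parent = paste0("mRNA:", orf$transcript_id),
                            Name = orf$orf_id)))
    }
    oev <- ev[ev$protein_id == orf$orf_id, , drop = FALSE]
    for (j in seq_len(nrow(oev))) {
      gp <- project_peptide(oev[j, ], orf, aln)
      if (inherits(gp, "unprojectable_peptide")) {
        unprojectable <- c(unprojectable, gp$reason)
        next
      }
      pep_serial <- pep_serial + 1L
      pid <- sprintf("pep:%06d", pep_serial)
      q <- unname(qv[gp$peptide])
      gfeatures[[length(gfeatures) + 1L]] <- gp
      feats[[length(feats) + 1L]] <- gff3_features(
        gp$seqid, source, "peptide",
        gp$segments[, "start"] + 1L, gp$segments[, "end"],
        score = if (length(q) && !is.na(q)) q else NA_real_,
        strand = gp$strand, phase = gp$frame_phase,
        attributes = rep(list(c(ID = pid, Parent = orf_feature_id,
                                Name = gp$peptide)), nrow(gp$segments)))
      cg <- to_cigar(gp$segments, gp$strand)
      seq_out <- if (!is.null(genome)) {
        gs <- genome$sequence[match(gp$seqid, genome$id)]
        coding <- extract_feature_sequence(gs, gp$segments, gp$strand)
        # SAM stores the forward-genome-strand bases
        if (gp$strand == "-") reverse_complement(coding) else coding
      } else "*"
      sams[[length(sams) + 1L]] <- sam_records(
        pid, cg$flag, gp$seqid, cg$pos, cg$cigar, seq_out)
      tabs[[length(tabs) + 1L]] <- data.frame(
        peptide = gp$peptide, orf_id = gp$orf_id,
        transcript_id = gp$transcript_id, seqid = gp$seqid,
        strand = gp$strand,
        segments = paste(paste0(gp$segments[, "start"] + 1L, "-",
                                gp$segments[, "end"]), collapse = ","),
        q_value = if (length(q)) q else NA_real_, stringsAsFactors = FALSE)
    }
  }
  if (length(dangling))
    unprojectable <- c(unprojectable,
                       sprintf("transcript %s has no alignment", dangling))
  gff <- do.call(rbind, c(list(gff3_features(character(), character(),
                                             character(), integer(),
                                             integer())[0, ]), feats))
  sam <- do.call(rbind, c(list(sam_records(character(), integer(),
                                           character(), integer(),
                                           character())), sams))
  tab <- do.call(rbind, c(list(data.frame(
    peptide = character(), orf_id = character(), transcript_id = character(),
    seqid = character(), strand = character(), segments = character(),
    q_value = numeric(), stringsAsFactors = FALSE)), tabs))
  ref_len <- if (!is.null(genome))
    structure(nchar(genome$sequence), names = genome$id)
  else {
    top <- vapply(split(gff$end, gff$seqid), max, numeric(1))
    structure(as.integer(top), names = names(top))
  }
  structure(list(
    gff = gff, sam = sam, reference_lengths = ref_len, table = tab,
    features = gfeatures,
    report = list(n_transcripts = length(used_tr),
                  n_orfs = nrow(orfs),
                  n_peptide_features = pep_serial,
                  n_unprojectable = length(unprojectable),
                  unprojectable = unprojectable)),
    class = "annotation_bundle")
}

#' @export
print.annotation_bundle <- function(x, ...) {
  r <- x$report
  cat("Genome annotation bundle:", r$n_transcripts, "transcript(s),",
      r$n_orfs, "ORF(s),", r$n_peptide_features, "peptide feature(s),",
      r$n_unprojectable, "unprojectable item(s)\n")
  invisible(x)
}

#' Write an annotation bundle to GFF3, SAM and TSV files
#'
#' @param bundle An `annotation_bundle` from [integrate_annotations()].
#' @param gff3,sam,table Output paths (`NULL` to skip).
#' @export
write_annotation_bundle <- function(bundle, gff3 = NULL, sam = NULL,
                                    table = NULL) {
  if (!is.null(gff3)) write_gff3(bundle$gff, gff3)
  if (!is.null(sam)) write_sam(bundle$sam, bundle$reference_lengths, sam)
  if (!is.null(table))
    utils::write.table(bundle$table, table, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(bundle)
}
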