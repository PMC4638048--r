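#' Construct a spliced transcript-to-genome alignment
#'
#' An alignment is an ordered set of exon blocks mapping transcript
#' coordinates to genome coordinates. All coordinates are 0-based half-open.
#' Blocks are stored ordered by transcript coordinate: the transcript
#' intervals are contiguous and tile `[0, aligned_length)`. On strand `"+"`
#' genome intervals ascend with transcript coordinate; on strand `"-"`
#' transcript coordinate 0 falls in the block with the largest genome
#' coordinate, and positions within each block run against the genome axis.
#'
#' @param transcript_id Transcript accession.
#' @param seqid Genome sequence name.
#' @param strand `"+"` or `"-"`.
#' @param blocks Numeric matrix with columns `t_start`, `t_end`, `g_start`,
#'   `g_end` (0-based half-open; equal lengths on both sides).
#' @return An object of class `transcript_alignment`.
#' @export
transcript_alignment <- function(transcript_id, seqid, strand, blocks) {
  blocks <- matrix(as.integer(blocks), ncol = 4,
                   dimnames = list(NULL, c("t_start", "t_end",
                                           "g_start", "g_end")))
  blocks <- blocks[order(blocks[, "t_start"]), , drop = FALSE]
  aln <- structure(list(transcript_id = transcript_id, seqid = seqid,
                        strand = strand, blocks = blocks),
                   class = "transcript_alignment")
  validate_alignment(aln)
  aln
}

validate_alignment <- function(aln) {
  b <- aln$blocks
  if (!aln$strand %in% c("+", "-"))
    stop("alignment ", aln$transcript_id, ": strand must be + or -")
  if (!nrow(b)) stop("alignment ", aln$transcript_id, ": no blocks")
  tl <- b[, "t_end"] - b[, "t_start"]
  gl <- b[, "g_end"] - b[, "g_start"]
  if (any(tl <= 0L) || any(tl != gl))
    stop("alignment ", aln$transcript_id,
         ": block transcript/genome lengths disagree")
  if (b[1, "t_start"] != 0L ||
      any(b[-1, "t_start"] != b[-nrow(b), "t_end"]))
    stop("alignment ", aln$transcript_id,
         ": transcript intervals must be contiguous from 0")
  g <- b[order(b[, "g_start"]), , drop = FALSE]
  if (any(g[-1, "g_start"] < g[-nrow(g), "g_end"]))
    stop("alignment ", aln$transcript_id, ": overlapping genome blocks")
  if (nrow(b) > 1) {
    ascending <- all(diff(b[, "g_start"]) > 0)
    descending <- all(diff(b[, "g_start"]) < 0)
    if (aln$strand == "+" && !ascending)
      stop("alignment ", aln$transcript_id,
           ": + strand requires genome blocks ascending with transcript")
    if (aln$strand == "-" && !descending)
      stop("alignment ", aln$transcript_id,
           ": - strand requires genome blocks descending with transcript")
  }
  invisible(aln)
}

aligned_length <- function(aln) {
  b <- aln$blocks
  as.integer(b[nrow(b), "t_end"])
}

#' @export
print.transcript_alignment <- function(x, ...) {
  cat("Spliced alignment", x$transcript_id, "->", x$seqid,
      paste0("(", x$strand, "), "), nrow(x$blocks), "block(s),",
      aligned_length(x), "nt aligned\n")
  invisible(x)
}

#' Read spliced transcript alignments from GFF3/GTF exon features
#'
#' Exon-type features are grouped per transcript using, in priority order,
#' the `Parent` attribute, the `transcript_id` attribute, or the first token
#' of the `Target` attribute. Transcript-side coordinates are reconstructed
#' from cumulative exon lengths honoring strand: on `-`, transcript
#' coordinate 0 corresponds to the highest genome coordinate. Transcripts
#' whose exons mix seqids or strands, or whose exons overlap, are rejected
#' with a per-transcript diagnostic rather than an error.
#'
#' @param path GFF3 or GTF file with exon features (GMAP-style output).
#' @return A list with `alignments` (named list of
#'   [transcript_alignment()] objects, in order of first appearance) and
#'   `rejected` (a `data.frame` with columns `transcript_id`, `reason`).
#' @export
read_transcript_alignments <- function(path) {
  feats <- read_gff3(path)
  feats <- feats[feats$type == "exon", , drop = FALSE]
  tid <- vapply(feats$attributes, function(at) {
    if ("Parent" %in% names(at)) at[["Parent"]]
    else if ("transcript_id" %in% names(at)) at[["transcript_id"]]
    else if ("Target" %in% names(at)) strsplit(at[["Target"]], "\\s+")[[1]][1]
    else NA_character_
  }, character(1))
  rejected <- data.frame(transcript_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  if (anyNA(tid)) {
    rejected <- rbind(rejected, data.frame(
      transcript_id = "<unattributed>",
      reason = paste(sum(is.na(tid)), "exon(s) without a transcript identifier"),
      stringsAsFactors = FALSE))
    feats <- feats[!is.na(tid), , drop = FALSE]
    tid <- tid[!is.na(tid)]
  }
  alignments <- list()
  for (t in unique(tid)) {
    ex <- feats[tid == t, , drop = FALSE]
    reason <- NULL
    if (length(unique(ex$seqid)) > 1L) reason <- "exons on mixed seqids"
    else if (length(unique(ex$strand)) > 1L) reason <- "exons on mixed strands"
    else if (!all(ex$strand %in% c("+", "-"))) reason <- "exon strand missing"
    else {
      ex <- ex[order(ex$start), , drop = FALSE]
      if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)]))
        reason <- "overlapping exon blocks"
    }
    if (!is.null(reason)) {
      rejected <- rbind(rejected, data.frame(transcript_id = t, reason = reason,
                                             stringsAsFactors = FALSE))
      next
    }
    g_start <- ex$start - 1L    # to 0-based half-open
    g_end <- ex$end
    lens <- g_end - g_start
    if (ex$strand[1] == "+") {
      t_start <- cumsum(c(0L, lens[-length(lens)]))
    } else {
      # transcript runs from the genomically last exon backwards
      rl <- rev(lens)
      t_start_rev <- cumsum(c(0L, rl[-length(rl)]))
      t_start <- rev(t_start_rev)
    }
    alignments[[t]] <- transcript_alignment(
      t, ex$seqid[1], ex$strand[1],
      cbind(t_start, t_start + lens, g_start, g_end))
  }
  list(alignments = alignments, rejected = rejected)
}
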