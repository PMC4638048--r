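#' Reverse complement of nucleotide strings
#'
#' @param x Character vector of sequences over `A,C,G,T,U,N` (case folded).
#' @return Character vector of reverse complements (uppercase, `U` mapped
#'   via `A`).
#' @export
reverse_complement <- function(x) {
  vapply(toupper(x), function(s) {
    chartr("ACGTUN", "TGCAAN", intToUtf8(rev(utf8ToInt(s))))
  }, character(1), USE.NAMES = FALSE)
}

codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- Biostrings::GENETIC_CODE
    tab
  }
})

#' Translate a nucleotide sequence (standard genetic code)
#'
#' Uses the standard genetic code (translation table 1). Codons containing
#' `N` (or any character outside `A,C,G,T`) translate to `X`; stop codons
#' translate to `*`. `U` is normalized to `T` and case is folded.
#'
#' @param nt Nucleotide string whose length is divisible by 3.
#' @return Amino-acid string of length `nchar(nt)/3`.
#' @export
translate <- function(nt) {
  nt <- chartr("U", "T", toupper(nt))
  n <- nchar(nt)
  if (n %% 3L != 0L)
    stop("sequence length ", n, " is not divisible by 3")
  if (n == 0L) return("")
  codons <- substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- codon_table()[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

normalize_transcript <- function(sequence, id = "<transcript>") {
  s <- chartr("Uu", "Tt", toupper(sequence))
  if (!nzchar(s)) stop("transcript ", id, ": empty sequence")
  if (grepl("[^ACGTN]", s))
    stop("transcript ", id, ": alphabet must be A,C,G,T,N (U folded to T)")
  s
}

#' Find open reading frames in all six frames of a transcript
#'
#' Frames `+1/+2/+3` read the forward sequence at offsets 0/1/2; `-1/-2/-3`
#' read the reverse complement at offsets 0/1/2. Within a frame, candidate
#' ORFs are maximal stop-free codon runs, closed by a stop codon or — when
#' `allow_partial` — by the transcript end. With `require_start` a candidate
#' is trimmed to its first ATG codon (candidates without one are dropped).
#' Codons containing `N` translate to `X` and do not terminate a run;
#' candidates that are more than 50% `X` are discarded. Reported coordinates
#' are always on the forward transcript strand, 0-based half-open, and
#' exclude the stop codon.
#'
#' @param sequence Transcript nucleotide sequence (`A,C,G,T,N`; `U` folded).
#' @param id Transcript accession used in ORF identifiers.
#' @param min_aa Minimum ORF length in residues (default 20).
#' @param mode `"per-frame-longest"` keeps at most one ORF per frame (the
#'   longest candidate of at least `min_aa` residues, ties broken by the
#'   smaller forward-strand `nt_start`); `"all-above-min"` keeps every
#'   candidate of at least `min_aa` residues.
#' @param require_start Require the ORF to begin with an ATG-encoded
#'   methionine (default `FALSE`; de novo transcripts are often fragments).
#' @param allow_partial Allow ORFs open at the transcript ends (default
#'   `TRUE`).
#' @return A `data.frame` with columns `orf_id`
#'   (`"<id>|F<frame>|<ordinal>"`, ordinals per frame in order of
#'   `nt_start`), `transcript_id`, `frame` (integer in `+1..+3`, `-1..-3`),
#'   `nt_start`, `nt_end`, `length_aa`, `aa`, `partial5`, `partial3`,
#'   ordered by `nt_start`.
#' @export
find_orfs <- function(sequence, id = "transcript", min_aa = 20L,
                      mode = c("per-frame-longest", "all-above-min"),
                      require_start = FALSE, allow_partial = TRUE) {
  mode <- match.arg(mode)
  if (min_aa < 1L) stop("min_aa must be >= 1")
  s <- normalize_transcript(sequence, id)
  L <- nchar(s)
  rc <- reverse_complement(s)
  rows <- list()
  for (strand in c(1L, -1L)) {
    src <- if (strand == 1L) s else rc
    for (off in 0:2) {
      ncod <- (L - off) %/% 3L
      if (ncod < 1L) next
      aa_all <- strsplit(translate(substr(src, off + 1L, off + 3L * ncod)),
                         "")[[1]]
      frame <- strand * (off + 1L)
      cands <- frame_candidates(aa_all, src, off, ncod, require_start,
                                allow_partial)
      if (!length(cands)) next
      for (cd in cands) {
        # local (reading-strand) nt coordinates
        a <- off + 3L * (cd$i0 - 1L)
        b <- off + 3L * cd$i1
        if (strand == 1L) {
          nt_start <- a; nt_end <- b
        } else {
          nt_start <- L - b; nt_end <- L - a
        }
        rows[[length(rows) + 1L]] <- data.frame(
          transcript_id = id, frame = frame,
          nt_start = nt_start, nt_end = nt_end,
          length_aa = cd$i1 - cd$i0 + 1L, aa = cd$aa,
          partial5 = cd$partial5, partial3 = cd$partial3,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty_orfs())
  orfs <- do.call(rbind, rows)
  orfs <- orfs[orfs$length_aa >= min_aa, , drop = FALSE]
  if (mode == "per-frame-longest" && nrow(orfs)) {
    keep <- unlist(lapply(split(seq_len(nrow(orfs)), orfs$frame), function(ix) {
      sub <- orfs[ix, ]
      ix[order(-sub$length_aa, sub$nt_start)][1L]
    }), use.names = FALSE)
    orfs <- orfs[sort(keep), , drop = FALSE]
  }
  if (!nrow(orfs)) return(empty_orfs())
  orfs <- orfs[order(orfs$nt_start, orfs$frame), , drop = FALSE]
  ord <- stats::ave(orfs$nt_start, orfs$frame, FUN = seq_along)
  orfs$orf_id <- sprintf("%s|F%+d|%d", orfs$transcript_id, orfs$frame,
                         as.integer(ord))
  rownames(orfs) <- NULL
  orfs[, c("orf_id", "transcript_id", "frame", "nt_start", "nt_end",
           "length_aa", "aa", "partial5", "partial3")]
}

# Maximal stop-free runs in one frame, with trimming/partial bookkeeping.
# Codon indices i0..i1 are 1-based within the frame.
frame_candidates <- function(aa_all, src, off, ncod, require_start,
                             allow_partial) {
  is_stop <- aa_all == "*"
  r <- rle(is_stop)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in seq_along(r$values)) {
    if (r$values[k]) next
    i0 <- starts[k]; i1 <- ends[k]
    partial5 <- i0 == 1L
    partial3 <- i1 == ncod            # run hit the frame end, no stop
    if (require_start) {
      codon_start <- off + 3L * (seq(i0, i1) - 1L) + 1L
      codons <- substring(src, codon_start, codon_start + 2L)
      atg <- which(codons == "ATG")
      if (!length(atg)) next
      i0 <- i0 + atg[1L] - 1L
      partial5 <- FALSE
    }
    if (!allow_partial && (partial5 || partial3)) next
    aa <- paste(aa_all[i0:i1], collapse = "")
    nx <- sum(aa_all[i0:i1] == "X")
    if (nx * 2L > (i1 - i0 + 1L)) next   # >50% ambiguous: junk
    out[[length(out) + 1L]] <- list(i0 = i0, i1 = i1, aa = aa,
                                    partial5 = partial5, partial3 = partial3)
  }
  out
}

empty_orfs <- function() {
  data.frame(orf_id = character(), transcript_id = character(),
             frame = integer(), nt_start = integer(), nt_end = integer(),
             length_aa = integer(), aa = character(), partial5 = logical(),
             partial3 = logical(), stringsAsFactors = FALSE)
}

#' Build a six-frame ORF protein database from transcripts
#'
#' One FASTA record is emitted per ORF found by [find_orfs()]; the record id
#' is the `orf_id` and the description encodes the provenance fields
#' (transcript, frame, forward-strand coordinates, partial flags). The
#' companion index table carries the same provenance so that downstream
#' genome projection can recover transcript coordinates.
#'
#' @param transcripts FASTA record frame of transcripts (unique ids).
#' @inheritParams find_orfs
#' @return A list with `db` (FASTA record frame of protein sequences) and
#'   `index` (the ORF provenance table, one row per record).
#' @export
build_orf_database <- function(transcripts, min_aa = 20L,
                               mode = c("per-frame-longest", "all-above-min"),
                               require_start = FALSE, allow_partial = TRUE) {
  mode <- match.arg(mode)
  if (anyDuplicated(transcripts$id))
    stop("duplicate transcript id(s): ",
         paste(unique(transcripts$id[duplicated(transcripts$id)]),
               collapse = ", "))
  per <- lapply(seq_len(nrow(transcripts)), function(i)
    find_orfs(transcripts$sequence[i], transcripts$id[i], min_aa = min_aa,
              mode = mode, require_start = require_start,
              allow_partial = allow_partial))
  index <- do.call(rbind, c(list(empty_orfs()), per))
  rownames(index) <- NULL
  db <- if (nrow(index)) fasta_records(
    id = index$orf_id,
    sequence = index$aa,
    description = sprintf(
      "transcript=%s frame=%+d nt_start=%d nt_end=%d partial5=%s partial3=%s",
      index$transcript_id, index$frame, index$nt_start, index$nt_end,
      index$partial5, index$partial3)) else fasta_empty()
  list(db = db, index = index)
}

#' Write/read an ORF provenance index table
#'
#' @param index ORF index frame from [build_orf_database()].
#' @param path TSV path.
#' @export
write_orf_index <- function(index, path) {
  utils::write.table(index, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_orf_index
#' @export
read_orf_index <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("orf_id", "transcript_id", "frame", "nt_start", "nt_end", "aa")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("ORF index ", path, ": missing column(s): ",
         paste(miss, collapse = ", "))
  tab
}
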