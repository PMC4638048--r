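#' Construct a set of FASTA records
#'
#' FASTA sequence sets are represented throughout the package as a plain
#' `data.frame` with character columns `id` (accession: the first
#' whitespace-delimited token of the header), `description` (remainder of the
#' header, possibly empty) and `sequence`.
#'
#' @param id Character vector of accessions. Must be non-empty and unique.
#' @param sequence Character vector of residue strings (nucleotide or amino
#'   acid), one per id. Must be non-empty.
#' @param description Character vector of free-text descriptions, recycled.
#' @return A `data.frame` with columns `id`, `description`, `sequence`.
#' @export
fasta_records <- function(id, sequence, description = "") {
  id <- as.character(id)
  sequence <- as.character(sequence)
  description <- rep_len(as.character(description), length(id))
  recs <- data.frame(id = id, description = description, sequence = sequence,
                     stringsAsFactors = FALSE)
  validate_fasta(recs)
  recs
}

validate_fasta <- function(recs, where = "FASTA records") {
  if (!all(c("id", "description", "sequence") %in% names(recs)))
    stop(where, ": need columns id, description, sequence")
  if (any(!nzchar(recs$id)))
    stop(where, ": empty record id")
  dup <- recs$id[duplicated(recs$id)]
  if (length(dup))
    stop(where, ": duplicate id(s): ", paste(unique(dup), collapse = ", "))
  if (any(!nzchar(recs$sequence)))
    stop(where, ": empty sequence for id(s): ",
         paste(recs$id[!nzchar(recs$sequence)], collapse = ", "))
  invisible(recs)
}

#' Read a FASTA file
#'
#' Headers are `>`-prefixed; multi-line sequences are concatenated and
#' whitespace inside sequence lines is removed. CRLF line endings are
#' tolerated. A sequence line appearing before any header, a duplicate
#' accession, or a header with no sequence is a format error.
#'
#' @param path Path to a FASTA file.
#' @return A `data.frame` of records as produced by [fasta_records()], in
#'   file order. An empty file yields a zero-row frame.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  keep <- nzchar(trimws(lines))
  line_no <- seq_along(lines)[keep]
  lines <- lines[keep]
  if (!length(lines))
    return(fasta_empty())
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L])
    stop("FASTA format error: sequence line before any header at line ",
         line_no[1L])
  grp <- cumsum(is_hdr)
  headers <- sub("^>", "", lines[is_hdr])
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  seqs <- vapply(split(lines[!is_hdr], factor(grp[!is_hdr], levels = seq_along(id))),
                 function(x) gsub("[ \t]", "", paste(x, collapse = "")),
                 character(1), USE.NAMES = FALSE)
  recs <- data.frame(id = id, description = description, sequence = seqs,
                     stringsAsFactors = FALSE)
  validate_fasta(recs, where = path)
  recs
}

fasta_empty <- function() {
  data.frame(id = character(), description = character(),
             sequence = character(), stringsAsFactors = FALSE)
}

#' Write FASTA records
#'
#' @param recs Record frame as produced by [fasta_records()] or [read_fasta()].
#' @param path Output path.
#' @param width Line width for wrapping sequences (default 60).
#' @export
write_fasta <- function(recs, path, width = 60L) {
  validate_fasta(recs)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(recs))) {
    hdr <- if (nzchar(recs$description[i]))
      paste(recs$id[i], recs$description[i]) else recs$id[i]
    writeLines(paste0(">", hdr), con)
    s <- recs$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
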