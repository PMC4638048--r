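#' Reference length consumed by a CIGAR string
#'
#' Sums the lengths of reference-consuming operations (M, D, N, =, X).
#'
#' @param cigar CIGAR string, e.g. `"4M90N5M"`.
#' @return Integer reference span.
#' @export
cigar_reference_length <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(0L)
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    if (!length(ops) || nchar(paste(ops, collapse = "")) != nchar(cg))
      stop("malformed CIGAR: ", cg)
    lens <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    kind <- sub("^[0-9]+", "", ops)
    sum(lens[kind %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Construct SAM alignment records
#'
#' @param qname Query names.
#' @param flag Integer FLAG field (bit 16 = reverse strand).
#' @param rname Reference names.
#' @param pos 1-based leftmost mapping positions.
#' @param cigar CIGAR strings.
#' @param seq Segment sequences (`"*"` when unavailable).
#' @param mapq Mapping quality (default 255 = unavailable).
#' @return A `data.frame` of records.
#' @export
sam_records <- function(qname, flag, rname, pos, cigar, seq = "*",
                        mapq = 255L) {
  n <- length(qname)
  data.frame(qname = as.character(qname), flag = as.integer(flag),
             rname = as.character(rname), pos = as.integer(pos),
             mapq = rep_len(as.integer(mapq), n),
             cigar = as.character(cigar),
             seq = rep_len(as.character(seq), n),
             stringsAsFactors = FALSE)
}

#' Write alignment records to a SAM file
#'
#' Emits an `@HD` header and one `@SQ` line per reference, then the eleven
#' mandatory columns per record (RNEXT/PNEXT/TLEN/QUAL unset). Each record's
#' reference-consumed length must fit within the named reference.
#'
#' @param records Record frame from [sam_records()].
#' @param reference_lengths Named integer vector of reference sequence
#'   lengths.
#' @param path Output path.
#' @export
write_sam <- function(records, reference_lengths, path) {
  if (is.null(names(reference_lengths)) || any(!nzchar(names(reference_lengths))))
    stop("reference_lengths must be a named vector")
  unknown <- setdiff(unique(records$rname), names(reference_lengths))
  if (length(unknown))
    stop("SAM record(s) reference unknown sequence(s): ",
         paste(unknown, collapse = ", "), " (first offending qname: ",
         records$qname[records$rname %in% unknown][1L], ")")
  span <- cigar_reference_length(records$cigar)
  over <- which(records$pos < 1L |
                  records$pos - 1L + span >
                  reference_lengths[records$rname])
  if (length(over))
    stop("SAM record extends past reference end: qname ",
         records$qname[over[1L]])
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(reference_lengths),
                  "\tLN:", as.integer(reference_lengths)))
  body <- if (nrow(records)) paste(records$qname, records$flag, records$rname,
                                   records$pos, records$mapq, records$cigar,
                                   "*", 0L, 0L, records$seq, "*",
                                   sep = "\t") else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SAM file (mandatory fields)
#'
#' Minimal reader for the package's own output: returns the eleven mandatory
#' columns plus the header reference lengths as an attribute.
#'
#' @param path Path to a SAM file.
#' @return Record frame (see [sam_records()]) with attribute
#'   `reference_lengths`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  sq <- hdr[startsWith(hdr, "@SQ")]
  refs <- structure(
    as.integer(sub("^.*\tLN:([0-9]+).*$", "\\1", sq)),
    names = sub("^.*\tSN:([^\t]+).*$", "\\1", sq))
  if (!length(body)) {
    out <- sam_records(character(), integer(), character(), integer(),
                       character())
  } else {
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(parts) < 11L))
      stop("SAM ", path, ": fewer than 11 columns at record ",
           which(lengths(parts) < 11L)[1L])
    col <- function(i) vapply(parts, `[[`, character(1), i)
    out <- sam_records(col(1), as.integer(col(2)), col(3),
                       as.integer(col(4)), col(6), col(10),
                       as.integer(col(5)))
  }
  attr(out, "reference_lengths") <- refs
  out
}
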