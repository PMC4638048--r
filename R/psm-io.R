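#' Read a peptide-spectrum-match table
#'
#' The PSM interchange format is a tab-separated table with a header row.
#' Mandatory columns: `spectrum_id`, `peptide`, `score`. Optional columns:
#' `modifications` (free text, empty when absent), `proteins`
#' (semicolon-joined accessions), `is_decoy` (logical). Decoy status, when no
#' `is_decoy` column is present, is derived later from the protein accession
#' prefix (see [peptide_level_scores()]).
#'
#' @param path Path to the TSV file.
#' @param higher_is_better Score orientation recorded on the result as the
#'   attribute `higher_is_better` (default `TRUE`: larger scores are better).
#' @return A `data.frame` with columns `spectrum_id`, `peptide`,
#'   `modifications`, `score`, `proteins`, and `is_decoy` (logical, `NA` when
#'   not supplied).
#' @export
read_psm_table <- function(path, higher_is_better = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("spectrum_id", "peptide", "score")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("PSM table ", path, ": missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  score <- suppressWarnings(as.numeric(tab$score))
  bad <- which(!is.finite(score))
  if (length(bad))
    stop("PSM table ", path, ": unparseable score at data line ",
         bad[1L], " (file line ", bad[1L] + 1L, "): '", tab$score[bad[1L]], "'")
  if (nrow(tab) && any(!grepl("^[A-Z]+$", tab$peptide)))
    stop("PSM table ", path, ": peptide not matching [A-Z]+ at data line ",
         which(!grepl("^[A-Z]+$", tab$peptide))[1L])
  out <- data.frame(
    spectrum_id = tab$spectrum_id,
    peptide = tab$peptide,
    modifications = if ("modifications" %in% names(tab)) tab$modifications else "",
    score = score,
    proteins = if ("proteins" %in% names(tab)) tab$proteins else "",
    is_decoy = if ("is_decoy" %in% names(tab))
      as.logical(tab$is_decoy) else NA,
    stringsAsFactors = FALSE)
  attr(out, "higher_is_better") <- higher_is_better
  out
}

#' Write a peptide-spectrum-match table
#'
#' @param psms PSM frame (see [read_psm_table()] for the columns).
#' @param path Output path.
#' @export
write_psm_table <- function(psms, path) {
  cols <- c("spectrum_id", "peptide", "modifications", "score", "proteins")
  for (nm in setdiff(cols, names(psms))) psms[[nm]] <- ""
  out <- psms[, c(cols, intersect("is_decoy", names(psms)))]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read BLAST tabular output (outfmt 6)
#'
#' Accepts the 12-column tab-separated BLAST report
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore). Columns beyond the twelfth are preserved verbatim in an
#' `extra` column (tab-joined). Lines with fewer than 12 columns are a format
#' error naming the line number.
#'
#' @param path Path to the tabular report.
#' @return A `data.frame` of hits in file order with numeric fields parsed.
#' @export
read_blast_tabular <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(blast_empty())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc < 12L))
    stop("BLAST tabular ", path, ": fewer than 12 columns at line ",
         which(nc < 12L)[1L])
  col <- function(i) vapply(parts, `[[`, character(1), i)
  hits <- data.frame(
    query_id = col(1), subject_id = col(2),
    pct_identity = as.numeric(col(3)), aln_length = as.integer(col(4)),
    mismatches = as.integer(col(5)), gap_opens = as.integer(col(6)),
    q_start = as.integer(col(7)), q_end = as.integer(col(8)),
    s_start = as.integer(col(9)), s_end = as.integer(col(10)),
    evalue = as.numeric(col(11)), bitscore = as.numeric(col(12)),
    extra = vapply(parts, function(p)
      if (length(p) > 12L) paste(p[-(1:12)], collapse = "\t") else "",
      character(1)),
    stringsAsFactors = FALSE)
  if (any(!is.finite(hits$evalue)) || any(hits$evalue < 0))
    stop("BLAST tabular ", path, ": invalid e-value at line ",
         which(!is.finite(hits$evalue) | hits$evalue < 0)[1L])
  if (any(hits$pct_identity < 0 | hits$pct_identity > 100))
    stop("BLAST tabular ", path, ": percent identity outside [0,100] at line ",
         which(hits$pct_identity < 0 | hits$pct_identity > 100)[1L])
  hits
}

blast_empty <- function() {
  data.frame(query_id = character(), subject_id = character(),
             pct_identity = numeric(), aln_length = integer(),
             mismatches = integer(), gap_opens = integer(),
             q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             evalue = numeric(), bitscore = numeric(),
             extra = character(), stringsAsFactors = FALSE)
}

#' Write BLAST tabular (outfmt 6) hits
#'
#' Inverse of [read_blast_tabular()]; used by the synthetic homology
#' generator.
#'
#' @param hits Hit frame (see [read_blast_tabular()]).
#' @param path Output path.
#' @export
write_blast_tabular <- function(hits, path) {
  lines <- vapply(seq_len(nrow(hits)), function(i) {
    base <- paste(hits$query_id[i], hits$subject_id[i],
                  format_num(hits$pct_identity[i]), hits$aln_length[i],
                  hits$mismatches[i], hits$gap_opens[i],
                  hits$q_start[i], hits$q_end[i], hits$s_start[i],
                  hits$s_end[i], format_num(hits$evalue[i]),
                  format_num(hits$bitscore[i]), sep = "\t")
    if (nzchar(hits$extra[i])) paste(base, hits$extra[i], sep = "\t") else base
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

format_num <- function(x) {
  # plain decimal for ordinary magnitudes, scientific for tiny e-values
  vapply(x, function(v) {
    if (v != 0 && abs(v) < 1e-4) format(v, scientific = TRUE, digits = 15)
    else format(v, scientific = FALSE, digits = 15)
  }, character(1))
}
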