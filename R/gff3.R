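#' Construct GFF3 features
#'
#' Features are held as a `data.frame` with the nine GFF3 columns; the
#' `attributes` column is a list of named character vectors preserving key
#' order. Coordinates here are already 1-based inclusive (the package's
#' internal 0-based half-open intervals are converted at emission time, see
#' [integrate_annotations()]).
#'
#' @param seqid,source,type Character vectors.
#' @param start,end Integer vectors, 1-based inclusive, `start <= end`.
#' @param score Numeric or `NA` for missing.
#' @param strand One of `"+"`, `"-"`, `"."`.
#' @param phase One of `0`, `1`, `2`, or `NA` (serialized as `.`).
#' @param attributes List of named character vectors (e.g.
#'   `list(c(ID = "pep1", Parent = "orf1"))`), recycled if length 1.
#' @return A GFF3 feature frame.
#' @export
gff3_features <- function(seqid, source, type, start, end, score = NA_real_,
                          strand = ".", phase = NA_integer_,
                          attributes = list(character())) {
  n <- length(seqid)
  feats <- data.frame(seqid = as.character(seqid),
                      source = rep_len(as.character(source), n),
                      type = rep_len(as.character(type), n),
                      start = as.integer(start), end = as.integer(end),
                      score = rep_len(as.numeric(score), n),
                      strand = rep_len(as.character(strand), n),
                      phase = rep_len(as.integer(phase), n),
                      stringsAsFactors = FALSE)
  if (length(attributes) == 1L && n != 1L)
    attributes <- rep(attributes, n)
  feats$attributes <- attributes
  validate_gff3(feats)
  feats
}

validate_gff3 <- function(feats) {
  bad <- which(!(feats$start >= 1L & feats$start <= feats$end))
  if (length(bad))
    stop("invalid GFF3 feature (need 1 <= start <= end): ",
         feature_label(feats, bad[1L]))
  bad <- which(!feats$strand %in% c("+", "-", "."))
  if (length(bad))
    stop("invalid GFF3 strand for feature ", feature_label(feats, bad[1L]))
  bad <- which(!(is.na(feats$phase) | feats$phase %in% 0:2))
  if (length(bad))
    stop("invalid GFF3 phase for feature ", feature_label(feats, bad[1L]))
  invisible(feats)
}

feature_label <- function(feats, i) {
  at <- feats$attributes[[i]]
  id <- if (!is.null(at) && "ID" %in% names(at)) at[["ID"]] else
    paste0(feats$seqid[i], ":", feats$start[i], "-", feats$end[i])
  paste0(id, " (row ", i, ")")
}

# Percent-escaping per the GFF3 attribute rules: the structural characters
# ';', '=', '&', ',', '%', tab and newline are encoded.
gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("\t", "%09", x, fixed = TRUE)
  gsub("\n", "%0A", x, fixed = TRUE)
}

gff3_unescape <- function(x) {
  if (!length(x)) return(character())
  vapply(x, utils::URLdecode, character(1), USE.NAMES = FALSE)
}

serialize_attrs <- function(at) {
  if (!length(at)) return(".")
  paste(paste0(names(at), "=", gff3_escape(unname(at))), collapse = ";")
}

#' Write features to a GFF3 file
#'
#' The file begins with the `##gff-version 3` pragma, followed by one
#' tab-separated nine-column line per feature. Attribute values are
#' percent-escaped; key order is preserved.
#'
#' @param feats Feature frame from [gff3_features()] or [read_gff3()].
#' @param path Output path.
#' @export
write_gff3 <- function(feats, path) {
  validate_gff3(feats)
  lines <- c("##gff-version 3", vapply(seq_len(nrow(feats)), function(i) {
    paste(feats$seqid[i], feats$source[i], feats$type[i],
          feats$start[i], feats$end[i],
          if (is.na(feats$score[i])) "." else format_num(feats$score[i]),
          feats$strand[i],
          if (is.na(feats$phase[i])) "." else feats$phase[i],
          serialize_attrs(feats$attributes[[i]]), sep = "\t")
  }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

# Parses one attribute column, accepting both the GFF3 `key=value;` and the
# GTF `key "value";` dialects.
parse_gff_attrs <- function(s) {
  s <- trimws(s)
  if (!nzchar(s) || s == ".") return(character())
  if (grepl("=", s, fixed = TRUE)) {
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    parts <- trimws(parts[nzchar(trimws(parts))])
    kv <- regmatches(parts, regexpr("=", parts, fixed = TRUE), invert = TRUE)
    vals <- gff3_unescape(vapply(kv, function(p) if (length(p) == 2) p[2] else "",
                                 character(1)))
    names(vals) <- vapply(kv, `[[`, character(1), 1)
    vals
  } else {
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    parts <- trimws(parts[nzchar(trimws(parts))])
    m <- regmatches(parts, regexec('^(\\S+)\\s+"?([^"]*)"?$', parts))
    vals <- vapply(m, function(p) if (length(p) == 3) p[3] else "", character(1))
    names(vals) <- vapply(m, function(p) if (length(p) == 3) p[2] else "", character(1))
    vals
  }
}

#' Read a GFF3 (or GTF) file into a feature frame
#'
#' Comment and pragma lines are skipped; both GFF3 `key=value` and GTF
#' `key "value"` attribute dialects are accepted. A feature with `end <
#' start` is a format error naming the line.
#'
#' @param path Path to the annotation file.
#' @return A feature frame (see [gff3_features()]).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  keep <- nzchar(lines) & !startsWith(lines, "#")
  line_no <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(gff3_features(character(), character(), character(),
                         integer(), integer())[0, ])
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc < 9L))
    stop("GFF ", path, ": fewer than 9 columns at line ", line_no[nc < 9L][1L])
  col <- function(i) vapply(parts, `[[`, character(1), i)
  start <- as.integer(col(4)); end <- as.integer(col(5))
  bad <- which(is.na(start) | is.na(end) | end < start | start < 1L)
  if (length(bad))
    stop("GFF ", path, ": invalid coordinates (end < start?) at line ",
         line_no[bad[1L]])
  sc <- col(6)
  ph <- col(8)
  feats <- data.frame(seqid = col(1), source = col(2), type = col(3),
                      start = start, end = end,
                      score = ifelse(sc == ".", NA_real_,
                                     suppressWarnings(as.numeric(sc))),
                      strand = col(7),
                      phase = ifelse(ph == ".", NA_integer_,
                                     suppressWarnings(as.integer(ph))),
                      stringsAsFactors = FALSE)
  feats$attributes <- lapply(col(9), parse_gff_attrs)
  feats
}
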