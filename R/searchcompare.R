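#' In-silico tryptic digest of a protein
#'
#' Cleaves C-terminal to K or R except when the next residue is P, and
#' returns every fully tryptic fragment with at most `missed_cleavages`
#' internal cleavage sites, filtered to the length window.
#'
#' @param protein Amino-acid string.
#' @param missed_cleavages Maximum internal missed cleavage sites
#'   (default 2).
#' @param min_len,max_len Peptide length window (defaults 7 and 45; use
#'   `min_len = 1, max_len = Inf` to disable).
#' @return Character vector of unique peptides.
#' @export
tryptic_digest <- function(protein, missed_cleavages = 2L, min_len = 7L,
                           max_len = 45L) {
  n <- nchar(protein)
  if (!n) return(character())
  aa <- strsplit(protein, "")[[1]]
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & aa[cut_after + 1L] != "P"]
  bounds <- c(0L, cut_after, n)
  m <- length(bounds) - 1L
  peps <- character()
  for (i in seq_len(m)) {
    jmax <- min(i + missed_cleavages, m)
    for (j in i:jmax) {
      len <- bounds[j + 1L] - bounds[i]
      if (len < min_len || len > max_len) next
      peps <- c(peps, substr(protein, bounds[i] + 1L, bounds[j + 1L]))
    }
  }
  unique(peps)
}

digest_universe <- function(db, missed_cleavages = 2L, min_len = 7L,
                            max_len = 45L, decoy_prefix = "DECOY_") {
  targets <- db[!startsWith(db$id, decoy_prefix), , drop = FALSE]
  unique(unlist(lapply(targets$sequence, tryptic_digest,
                       missed_cleavages = missed_cleavages,
                       min_len = min_len, max_len = max_len),
                use.names = FALSE))
}

#' Peptide overlap percentage (shared over union)
#'
#' `100 * shared / (shared + unique_a + unique_b)`, rounded to the nearest
#' integer; 0 when the union is empty.
#'
#' @param shared,unique_a,unique_b Counts.
#' @return Integer percentage.
#' @export
overlap_percent <- function(shared, unique_a, unique_b) {
  union <- shared + unique_a + unique_b
  if (union == 0) return(0L)
  as.integer(round(100 * shared / union))
}

#' Attribution percentage at one decimal place
#'
#' `round(100 * numerator / denominator, 1)`; `NA` for a zero denominator.
#'
#' @param numerator,denominator Counts.
#' @return Numeric percentage with one decimal.
#' @export
attribution_percent <- function(numerator, denominator) {
  if (denominator == 0) return(NA_real_)
  round(100 * numerator / denominator, 1)
}

#' Compare retained peptide lists from two searches
#'
#' Overlap is computed on plain (unmodified) sequences — only exact peptide
#' sequence matches count. For each search's unique peptides, membership in
#' the opposing database's in-silico tryptic peptide universe attributes
#' the uniqueness to database absence.
#'
#' @param retained_a,retained_b Character vectors of retained plain peptide
#'   sequences (duplicates ignored).
#' @param db_a,db_b Optional protein FASTA record frames; when supplied the
#'   absence attribution is computed for the opposing search.
#' @param missed_cleavages,min_len,max_len Digest parameters for the
#'   peptide universes (defaults 2, 7, 45).
#' @return An object of class `peptide_overlap_report`: counts `n_a`,
#'   `n_b`, `shared`, `unique_a`, `unique_b`, the integer `overlap_pct`,
#'   and attribution fields `absent_from_other_db_a/b` with
#'   `absent_pct_a/b` (1 decimal; `NA` when the opposing database was not
#'   supplied).
#' @export
compare_peptides <- function(retained_a, retained_b, db_a = NULL,
                             db_b = NULL, missed_cleavages = 2L,
                             min_len = 7L, max_len = 45L) {
  a <- unique(retained_a); b <- unique(retained_b)
  shared <- length(intersect(a, b))
  ua <- setdiff(a, b); ub <- setdiff(b, a)
  rep <- list(n_a = length(a), n_b = length(b), shared = shared,
              unique_a = length(ua), unique_b = length(ub),
              overlap_pct = overlap_percent(shared, length(ua), length(ub)),
              absent_from_other_db_a = NA_integer_,
              absent_pct_a = NA_real_,
              absent_from_other_db_b = NA_integer_,
              absent_pct_b = NA_real_)
  if (!is.null(db_b)) {
    uni_b <- digest_universe(db_b, missed_cleavages, min_len, max_len)
    rep$absent_from_other_db_a <- sum(!ua %in% uni_b)
    rep$absent_pct_a <- attribution_percent(rep$absent_from_other_db_a,
                                            length(ua))
  }
  if (!is.null(db_a)) {
    uni_a <- digest_universe(db_a, missed_cleavages, min_len, max_len)
    rep$absent_from_other_db_b <- sum(!ub %in% uni_a)
    rep$absent_pct_b <- attribution_percent(rep$absent_from_other_db_b,
                                            length(ub))
  }
  structure(rep, class = "peptide_overlap_report")
}

#' Build a peptide overlap report from printed totals
#'
#' For comparing against published summary tables: given the totals and
#' the unique counts of two searches, reconstructs the shared count
#' (checking consistency) and applies the same overlap formula as
#' [compare_peptides()].
#'
#' @param n_a,n_b Total retained peptides in each search.
#' @param unique_a,unique_b Peptides unique to each search.
#' @return A `peptide_overlap_report`.
#' @export
peptide_overlap_from_counts <- function(n_a, n_b, unique_a, unique_b) {
  shared_a <- n_a - unique_a
  shared_b <- n_b - unique_b
  if (shared_a != shared_b)
    stop("inconsistent counts: n_a - unique_a = ", shared_a,
         " but n_b - unique_b = ", shared_b)
  structure(list(n_a = n_a, n_b = n_b, shared = shared_a,
                 unique_a = unique_a, unique_b = unique_b,
                 overlap_pct = overlap_percent(shared_a, unique_a, unique_b),
                 absent_from_other_db_a = NA_integer_, absent_pct_a = NA_real_,
                 absent_from_other_db_b = NA_integer_, absent_pct_b = NA_real_),
            class = "peptide_overlap_report")
}

#' @export
print.peptide_overlap_report <- function(x, ...) {
  cat("Peptide overlap: ", x$shared, " shared / ", x$n_a, " vs ", x$n_b,
      " (", x$overlap_pct, "% of union); unique ", x$unique_a, " + ",
      x$unique_b, "\n", sep = "")
  if (!is.na(x$absent_pct_a))
    cat("  unique to A absent from B's digest: ", x$absent_from_other_db_a,
        " (", x$absent_pct_a, "%)\n", sep = "")
  if (!is.na(x$absent_pct_b))
    cat("  unique to B absent from A's digest: ", x$absent_from_other_db_b,
        " (", x$absent_pct_b, "%)\n", sep = "")
  invisible(x)
}

#' PAG match report from counts
#'
#' @param anchor_anchor,anchor_submember Match counts from the two passes.
#' @param unmatched_a,unmatched_b Unmatched PAG ids (or counts).
#' @param matches Optional match detail frame.
#' @return An object of class `pag_match_report` with `total_matches =
#'   anchor_anchor + anchor_submember` and the shared/union
#'   `pag_overlap_pct`.
#' @export
pag_match_report <- function(anchor_anchor, anchor_submember,
                             unmatched_a = character(),
                             unmatched_b = character(), matches = NULL) {
  total <- anchor_anchor + anchor_submember
  nu_a <- if (is.numeric(unmatched_a)) unmatched_a else length(unmatched_a)
  nu_b <- if (is.numeric(unmatched_b)) unmatched_b else length(unmatched_b)
  structure(list(anchor_anchor = anchor_anchor,
                 anchor_submember = anchor_submember,
                 total_matches = total,
                 unmatched_a = unmatched_a, unmatched_b = unmatched_b,
                 pag_overlap_pct = overlap_percent(total, nu_a, nu_b),
                 matches = matches),
            class = "pag_match_report")
}

#' @export
print.pag_match_report <- function(x, ...) {
  nu_a <- if (is.numeric(x$unmatched_a)) x$unmatched_a else length(x$unmatched_a)
  nu_b <- if (is.numeric(x$unmatched_b)) x$unmatched_b else length(x$unmatched_b)
  cat("PAG matching: ", x$anchor_anchor, " anchor-anchor + ",
      x$anchor_submember, " anchor-submember = ", x$total_matches,
      " match(es); unmatched ", nu_a, " + ", nu_b,
      " (overlap ", x$pag_overlap_pct, "%)\n", sep = "")
  invisible(x)
}

pag_members <- function(pags) {
  lapply(seq_len(nrow(pags)), function(i)
    unique(c(pags$anchor[i], pags$same_set[[i]], pags$sub_members[[i]])))
}

#' Match protein ambiguity groups across two searches by homology
#'
#' A homology hit qualifies if its e-value is strictly below the threshold.
#' Matching is greedy in two passes, each PAG usable at most once: pass 1
#' considers anchor-to-anchor hits, pass 2 anchor-to-(same-set or
#' sub-)member hits among still-unmatched PAGs. Within a pass, candidate
#' pairs are taken in ascending e-value order, ties broken by the sorted
#' accession pair.
#'
#' @param pags_a,pags_b `pag_set` objects (or their `pags` frames).
#' @param hits BLAST tabular hit frame ([read_blast_tabular()]); `query_id`
#'   accessions belong to search A, `subject_id` to search B. Hits naming
#'   unknown accessions are ignored with a diagnostic.
#' @param evalue_threshold Qualification threshold, strict (default
#'   `1e-30`).
#' @return A `pag_match_report` whose `matches` frame has columns `pag_a`,
#'   `pag_b`, `pass`, `evalue`, plus attribute `ignored_hits` (count).
#' @export
match_pags <- function(pags_a, pags_b, hits, evalue_threshold = 1e-30) {
  pa <- if (inherits(pags_a, "pag_set")) pags_a$pags else pags_a
  pb <- if (inherits(pags_b, "pag_set")) pags_b$pags else pags_b
  mem_a <- pag_members(pa); mem_b <- pag_members(pb)
  acc2pag_a <- stack_members(pa$pag_id, mem_a)
  acc2pag_b <- stack_members(pb$pag_id, mem_b)
  known <- hits$query_id %in% names(acc2pag_a) &
    hits$subject_id %in% names(acc2pag_b)
  ignored <- sum(!known)
  h <- hits[known & hits$evalue < evalue_threshold, , drop = FALSE]
  matched_a <- character(); matched_b <- character()
  matches <- list()
  if (nrow(h)) {
    h$pag_a <- unname(acc2pag_a[h$query_id])
    h$pag_b <- unname(acc2pag_b[h$subject_id])
    h$a_is_anchor <- h$query_id == pa$anchor[match(h$pag_a, pa$pag_id)]
    h$b_is_anchor <- h$subject_id == pb$anchor[match(h$pag_b, pb$pag_id)]
    # best (lowest) e-value per candidate pag pair within each pass class
    pairkey <- function(x, y) paste(pmin(x, y), pmax(x, y))
    for (pass in 1:2) {
      cand <- if (pass == 1) h[h$a_is_anchor & h$b_is_anchor, , drop = FALSE]
              else h[xor(h$a_is_anchor, h$b_is_anchor), , drop = FALSE]
      if (!nrow(cand)) next
      cand <- cand[order(cand$evalue, pairkey(cand$query_id, cand$subject_id)), ,
                   drop = FALSE]
      for (k in seq_len(nrow(cand))) {
        if (cand$pag_a[k] %in% matched_a || cand$pag_b[k] %in% matched_b)
          next
        matched_a <- c(matched_a, cand$pag_a[k])
        matched_b <- c(matched_b, cand$pag_b[k])
        matches[[length(matches) + 1L]] <- data.frame(
          pag_a = cand$pag_a[k], pag_b = cand$pag_b[k], pass = pass,
          evalue = cand$evalue[k], stringsAsFactors = FALSE)
      }
    }
  }
  md <- do.call(rbind, c(list(data.frame(pag_a = character(),
                                         pag_b = character(),
                                         pass = integer(), evalue = numeric(),
                                         stringsAsFactors = FALSE)), matches))
  rep <- pag_match_report(sum(md$pass == 1), sum(md$pass == 2),
                          setdiff(pa$pag_id, matched_a),
                          setdiff(pb$pag_id, matched_b), md)
  attr(rep, "ignored_hits") <- ignored
  rep
}

stack_members <- function(pag_ids, members) {
  # accession -> pag id; an accession appearing in several PAGs keeps the
  # first (creation-order) PAG, consistent with sub-member attachment
  acc <- unlist(members, use.names = FALSE)
  pid <- rep(pag_ids, lengths(members))
  keep <- !duplicated(acc)
  structure(pid[keep], names = acc[keep])
}

#' Classify PAGs left unmatched by the homology comparison
#'
#' Decision cascade, first hit wins:
#' 1. `isoform_of_matched` — a member of the PAG also belongs to a matched
#'    PAG on the same side;
#' 2. `no_transcript_evidence` — no transcript supports the anchor;
#' 3. `orf_failure` — transcripts exist but no ORF of the protein survived;
#' 4. `single_peptide_in_other_search` — the opposing search found the
#'    protein with exactly one peptide (below its two-peptide rule);
#' 5. `extended_orf` — the identified ORF strictly contains a reference
#'    protein and has peptide evidence outside the contained region;
#' 6. `no_known_homology` otherwise.
#'
#' A category whose auxiliary input is missing is disabled (recorded in the
#' `disabled` attribute), never a crash.
#'
#' @param unmatched_ids PAG ids to classify.
#' @param pag_set The side's `pag_set`.
#' @param matched_ids PAG ids on the same side that matched.
#' @param transcript_support Named logical: does transcript evidence exist
#'   for an accession?
#' @param surviving_orfs Character vector of accessions with surviving ORFs.
#' @param other_search_peptide_counts Named integer: distinct peptide count
#'   for the protein (or its homolog) in the opposing search.
#' @param orf_db,reference_db FASTA frames used for the extended-ORF check.
#' @param evidence Peptide evidence frame used for the extended-ORF check.
#' @return `data.frame` with columns `pag_id`, `category`; attribute
#'   `disabled` lists categories that could not be evaluated.
#' @export
classify_unmatched <- function(unmatched_ids, pag_set, matched_ids,
                               transcript_support = NULL,
                               surviving_orfs = NULL,
                               other_search_peptide_counts = NULL,
                               orf_db = NULL, reference_db = NULL,
                               evidence = NULL) {
  pags <- if (inherits(pag_set, "pag_set")) pag_set$pags else pag_set
  mem <- pag_members(pags)
  names(mem) <- pags$pag_id
  matched_universe <- unique(unlist(mem[intersect(matched_ids, pags$pag_id)],
                                    use.names = FALSE))
  disabled <- character()
  if (is.null(transcript_support)) disabled <- c(disabled, "no_transcript_evidence")
  if (is.null(transcript_support) || is.null(surviving_orfs))
    disabled <- c(disabled, "orf_failure")
  if (is.null(other_search_peptide_counts))
    disabled <- c(disabled, "single_peptide_in_other_search")
  if (is.null(orf_db) || is.null(reference_db) || is.null(evidence))
    disabled <- c(disabled, "extended_orf")
  out <- vapply(unmatched_ids, function(pid) {
    members <- mem[[pid]]
    anchor <- pags$anchor[pags$pag_id == pid]
    if (length(intersect(members, matched_universe)))
      return("isoform_of_matched")
    if (!is.null(transcript_support) &&
        !isTRUE(unname(transcript_support[anchor])))
      return("no_transcript_evidence")
    if (!is.null(transcript_support) && !is.null(surviving_orfs) &&
        !anchor %in% surviving_orfs)
      return("orf_failure")
    if (!is.null(other_search_peptide_counts) &&
        anchor %in% names(other_search_peptide_counts) &&
        other_search_peptide_counts[[anchor]] == 1L)
      return("single_peptide_in_other_search")
    if (!is.null(orf_db) && !is.null(reference_db) && !is.null(evidence) &&
        is_extended_orf(anchor, orf_db, reference_db, evidence))
      return("extended_orf")
    "no_known_homology"
  }, character(1), USE.NAMES = FALSE)
  res <- data.frame(pag_id = unmatched_ids, category = out,
                    stringsAsFactors = FALSE)
  attr(res, "disabled") <- disabled
  res
}

is_extended_orf <- function(anchor, orf_db, reference_db, evidence) {
  oseq <- orf_db$sequence[match(anchor, orf_db$id)]
  if (is.na(oseq)) return(FALSE)
  ev <- evidence[evidence$protein_id == anchor, , drop = FALSE]
  for (i in seq_len(nrow(reference_db))) {
    ref <- reference_db$sequence[i]
    if (nchar(ref) >= nchar(oseq)) next
    at <- regexpr(ref, oseq, fixed = TRUE)
    if (at == -1L) next
    lo <- as.integer(at) - 1L
    hi <- lo + nchar(ref)
    if (any(ev$start < lo | ev$end > hi)) return(TRUE)
  }
  FALSE
}
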