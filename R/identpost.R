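#' Append a reversed-sequence decoy to a protein database
#'
#' For each target record a decoy record is appended whose sequence is the
#' full reversal of the target and whose id carries the decoy prefix.
#' Reversal preserves length and amino-acid composition, so the decoy
#' score distribution calibrates the target-decoy FDR estimate. The output
#' is targets followed by decoys.
#'
#' @param records Protein FASTA record frame.
#' @param prefix Decoy accession prefix (default `"DECOY_"`).
#' @return FASTA record frame of targets then decoys.
#' @export
generate_decoy_database <- function(records, prefix = "DECOY_") {
  tainted <- startsWith(records$id, prefix)
  if (any(tainted))
    stop("target id(s) already carry the decoy prefix '", prefix, "': ",
         paste(records$id[tainted], collapse = ", "))
  if (!nrow(records)) return(records)
  decoys <- data.frame(
    id = paste0(prefix, records$id),
    description = paste("reversed", records$id),
    sequence = vapply(records$sequence,
                      function(s) intToUtf8(rev(utf8ToInt(s))),
                      character(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  rbind(records, decoys)
}

is_decoy_hint <- function(proteins, carried, prefix) {
  # A peptide matching both a target and a decoy protein counts as target.
  mapply(function(p, d) {
    if (nzchar(p)) {
      accs <- strsplit(p, ";", fixed = TRUE)[[1]]
      all(startsWith(accs, prefix))
    } else if (!is.na(d)) d else FALSE
  }, proteins, carried, USE.NAMES = FALSE)
}

#' Collapse PSMs to peptide-level scores
#'
#' PSMs are grouped by peptide key (sequence plus modification string); each
#' group keeps its best score under the configured orientation. Decoy status
#' per PSM is derived from the protein accessions when present (a peptide
#' matching any target protein counts as target), falling back on the
#' carried `is_decoy` flag.
#'
#' @param psms PSM frame (see [read_psm_table()]).
#' @param higher_is_better Score orientation (default `TRUE`).
#' @param decoy_prefix Accession prefix marking decoys.
#' @return A `data.frame` of scored peptides: `peptide_key`,
#'   `plain_sequence`, `modifications`, `best_score`, `supporting_spectra`,
#'   `is_decoy`.
#' @export
peptide_level_scores <- function(psms, higher_is_better = TRUE,
                                 decoy_prefix = "DECOY_") {
  if (!nrow(psms))
    return(data.frame(peptide_key = character(), plain_sequence = character(),
                      modifications = character(), best_score = numeric(),
                      supporting_spectra = integer(), is_decoy = logical(),
                      stringsAsFactors = FALSE))
  mods <- if ("modifications" %in% names(psms)) psms$modifications else ""
  mods[is.na(mods)] <- ""
  key <- ifelse(nzchar(mods), paste0(psms$peptide, "[", mods, "]"),
                psms$peptide)
  dec <- is_decoy_hint(if ("proteins" %in% names(psms)) psms$proteins else "",
                       if ("is_decoy" %in% names(psms)) psms$is_decoy else NA,
                       decoy_prefix)
  best <- if (higher_is_better) function(x) max(x) else function(x) min(x)
  idx <- split(seq_len(nrow(psms)), key)
  out <- data.frame(
    peptide_key = names(idx),
    plain_sequence = vapply(idx, function(i) psms$peptide[i[1L]], character(1)),
    modifications = vapply(idx, function(i) mods[i[1L]], character(1)),
    best_score = vapply(idx, function(i) best(psms$score[i]), numeric(1)),
    supporting_spectra = lengths(idx),
    is_decoy = vapply(idx, function(i) all(dec[i]), logical(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Compute peptide-level q-values by target-decoy competition
#'
#' Peptides are ranked best score first (score ties ordered decoys before
#' targets — the conservative choice). At each rank the false discovery
#' rate is estimated as `D/max(T,1)` with `D` and `T` the cumulative decoy
#' and target counts (the "simple FDR" convention; `estimator = "tdc"`
#' switches to `2D/(T+D)`). The q-value at a rank is the minimum estimated
#' FDR at that rank or below, capped at 1; peptides tied on score and decoy
#' status share a q-value.
#'
#' @param peptides Scored peptide frame from [peptide_level_scores()].
#' @param higher_is_better Score orientation (default `TRUE`).
#' @param estimator `"simple"` for `D/T` (default) or `"tdc"` for
#'   `2D/(T+D)`.
#' @return The peptide frame sorted best score first with a `q_value`
#'   column.
#' @export
compute_q_values <- function(peptides, higher_is_better = TRUE,
                             estimator = c("simple", "tdc")) {
  estimator <- match.arg(estimator)
  if (!nrow(peptides)) {
    peptides$q_value <- numeric(0)
    return(peptides)
  }
  s <- if (higher_is_better) -peptides$best_score else peptides$best_score
  ord <- order(s, !peptides$is_decoy)   # ties: decoys first
  p <- peptides[ord, , drop = FALSE]
  nd <- cumsum(p$is_decoy)
  nt <- cumsum(!p$is_decoy)
  fdr <- if (estimator == "simple") nd / pmax(nt, 1L)
         else 2 * nd / pmax(nt + nd, 1L)
  q <- pmin(rev(cummin(rev(fdr))), 1)
  grp <- paste(p$best_score, p$is_decoy)
  p$q_value <- stats::ave(q, grp, FUN = min)
  rownames(p) <- NULL
  p
}

#' Filter peptides at a q-value threshold
#'
#' Keeps target peptides with `q_value <= threshold`; decoys are excluded
#' from the reported list.
#'
#' @param peptides Peptide frame with q-values ([compute_q_values()]).
#' @param threshold Peptide-level FDR threshold in `[0, 1]` (default 0.01,
#'   the conventional 1%).
#' @return The retained target peptide frame.
#' @export
filter_peptides <- function(peptides, threshold = 0.01) {
  if (!is.numeric(threshold) || is.na(threshold) ||
      threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")
  if (!"q_value" %in% names(peptides))
    stop("peptides carry no q_value column; run compute_q_values() first")
  out <- peptides[!peptides$is_decoy & peptides$q_value <= threshold, ,
                  drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map peptides to proteins by exact substring occurrence
#'
#' Every exact occurrence (including overlapping occurrences) of each
#' peptide's plain sequence in each target protein is reported. Decoy
#' entries in the database are skipped. Peptides matching no protein are
#' returned in the `unmapped` diagnostics.
#'
#' @param peptides Retained peptide frame (needs `plain_sequence`; a
#'   `peptide_key` column is carried through when present).
#' @param database Protein FASTA record frame (e.g. the ORF database).
#' @param equate_il Treat I and L as indistinguishable (default `FALSE`).
#' @param decoy_prefix Database entries with this prefix are skipped.
#' @return A list with `evidence` (`data.frame`: `peptide_key`, `peptide`,
#'   `protein_id`, `start`, `end` — 0-based half-open offsets) and
#'   `unmapped` (character vector of peptide keys).
#' @export
map_peptides_to_proteins <- function(peptides, database, equate_il = FALSE,
                                     decoy_prefix = "DECOY_") {
  targets <- database[!startsWith(database$id, decoy_prefix), , drop = FALSE]
  pep <- unique(peptides$plain_sequence)
  keys <- if ("peptide_key" %in% names(peptides))
    peptides$peptide_key[match(pep, peptides$plain_sequence)] else pep
  seqs <- targets$sequence
  if (equate_il) {
    seqs_m <- chartr("I", "L", seqs)
    pep_m <- chartr("I", "L", pep)
  } else {
    seqs_m <- seqs; pep_m <- pep
  }
  rows <- vector("list", length(pep))
  found <- logical(length(pep))
  for (i in seq_along(pep)) {
    # lookahead regex finds overlapping occurrences
    pat <- paste0("(?=", pep_m[i], ")")
    hit <- lapply(seqs_m, function(s) {
      m <- gregexpr(pat, s, perl = TRUE)[[1]]
      if (m[1] == -1L) integer() else as.integer(m) - 1L
    })
    nh <- lengths(hit)
    if (any(nh > 0)) {
      found[i] <- TRUE
      rows[[i]] <- data.frame(
        peptide_key = keys[i], peptide = pep[i],
        protein_id = rep(targets$id, nh),
        start = unlist(hit, use.names = FALSE),
        end = unlist(hit, use.names = FALSE) + nchar(pep[i]),
        stringsAsFactors = FALSE)
    }
  }
  evidence <- do.call(rbind, c(list(data.frame(
    peptide_key = character(), peptide = character(),
    protein_id = character(), start = integer(), end = integer(),
    stringsAsFactors = FALSE)), rows[found]))
  rownames(evidence) <- NULL
  list(evidence = evidence, unmapped = keys[!found])
}

protein_peptide_sets <- function(evidence, count_modified = FALSE) {
  pcol <- if (count_modified && "peptide_key" %in% names(evidence))
    evidence$peptide_key else evidence$peptide
  lapply(split(pcol, evidence$protein_id), function(x) sort(unique(x)))
}

#' Group proteins into ambiguity groups (PAGs)
#'
#' Proteins are sorted by distinct peptide count (descending), ties broken
#' alphabetically by accession, and scanned in order. A protein whose
#' peptide set equals an existing group's anchor set joins that group as a
#' same-set member (equality is checked against every existing group before
#' subset attachment); a proper subset of an existing anchor set joins the
#' first qualifying group in creation order as a sub-member; otherwise the
#' protein founds a new group as its anchor. Groups whose anchor has fewer
#' than `min_peptides` distinct peptides are finally discarded (the
#' two-peptide rule at the default of 2), and peptides left without any
#' surviving group are reported as orphaned.
#'
#' @param evidence Peptide-to-protein evidence frame
#'   ([map_peptides_to_proteins()]).
#' @param min_peptides Minimum distinct peptides for a surviving anchor
#'   (default 2).
#' @param count_modified Count distinct modified peptide keys instead of
#'   plain sequences (default `FALSE`).
#' @return An object of class `pag_set`: list with `pags` (a `data.frame`
#'   with columns `pag_id`, `anchor`, `n_peptides` and list columns
#'   `same_set`, `sub_members`, `peptides`), `orphaned` (peptides whose
#'   every protein was discarded), and `min_peptides`.
#' @export
group_proteins <- function(evidence, min_peptides = 2L,
                           count_modified = FALSE) {
  sets <- protein_peptide_sets(evidence, count_modified)
  prots <- names(sets)
  if (!length(prots)) {
    return(structure(list(pags = empty_pags(), orphaned = character(),
                          min_peptides = min_peptides), class = "pag_set"))
  }
  ord <- order(-lengths(sets), prots)
  anchors <- character(); anchor_sets <- list()
  same <- list(); subs <- list()
  for (p in prots[ord]) {
    ps <- sets[[p]]
    eq <- which(vapply(anchor_sets, identical, logical(1), y = ps))
    if (length(eq)) {
      same[[eq[1L]]] <- c(same[[eq[1L]]], p)
      next
    }
    sub <- which(vapply(anchor_sets, function(a)
      length(ps) < length(a) && all(ps %in% a), logical(1)))
    if (length(sub)) {
      subs[[sub[1L]]] <- c(subs[[sub[1L]]], p)
      next
    }
    anchors <- c(anchors, p)
    anchor_sets[[length(anchors)]] <- ps
    same[[length(anchors)]] <- character()
    subs[[length(anchors)]] <- character()
  }
  keep <- lengths(anchor_sets) >= min_peptides
  pags <- data.frame(
    pag_id = sprintf("PAG_%d", seq_len(sum(keep))),
    anchor = anchors[keep],
    n_peptides = lengths(anchor_sets)[keep],
    stringsAsFactors = FALSE)
  pags$same_set <- same[keep]
  pags$sub_members <- subs[keep]
  pags$peptides <- anchor_sets[keep]
  covered <- unique(unlist(pags$peptides, use.names = FALSE))
  all_peps <- unique(unlist(sets, use.names = FALSE))
  structure(list(pags = pags,
                 orphaned = setdiff(all_peps, covered),
                 min_peptides = min_peptides),
            class = "pag_set")
}

empty_pags <- function() {
  pags <- data.frame(pag_id = character(), anchor = character(),
                     n_peptides = integer(), stringsAsFactors = FALSE)
  pags$same_set <- list(); pags$sub_members <- list(); pags$peptides <- list()
  pags
}

#' @export
print.pag_set <- function(x, ...) {
  cat("Protein ambiguity groups:", nrow(x$pags), "group(s) with >=",
      x$min_peptides, "distinct peptide(s)\n")
  if (nrow(x$pags)) {
    n <- min(nrow(x$pags), 10L)
    for (i in seq_len(n))
      cat(sprintf("  %s anchor=%s peptides=%d same_set=%d sub=%d\n",
                  x$pags$pag_id[i], x$pags$anchor[i], x$pags$n_peptides[i],
                  length(x$pags$same_set[[i]]),
                  length(x$pags$sub_members[[i]])))
    if (nrow(x$pags) > n) cat("  ...\n")
  }
  if (length(x$orphaned))
    cat(" ", length(x$orphaned),
        "peptide(s) orphaned by the minimum-peptide rule\n")
  invisible(x)
}

#' Write/read a PAG table
#'
#' Columns: `pag_id`, `anchor`, `same_set_members`, `sub_members`
#' (semicolon-joined), `n_peptides`, `peptides` (semicolon-joined).
#'
#' @param pag_set A `pag_set` object from [group_proteins()].
#' @param path TSV path.
#' @export
write_pag_table <- function(pag_set, path) {
  p <- pag_set$pags
  join <- function(col) vapply(col, paste, character(1), collapse = ";")
  tab <- data.frame(pag_id = p$pag_id, anchor = p$anchor,
                    same_set_members = join(p$same_set),
                    sub_members = join(p$sub_members),
                    n_peptides = p$n_peptides,
                    peptides = join(p$peptides), stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pag_table
#' @export
read_pag_table <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character",
                           stringsAsFactors = FALSE)
  split_col <- function(x) lapply(strsplit(x, ";", fixed = TRUE),
                                  function(v) v[nzchar(v)])
  pags <- data.frame(pag_id = tab$pag_id, anchor = tab$anchor,
                     n_peptides = as.integer(tab$n_peptides),
                     stringsAsFactors = FALSE)
  pags$same_set <- split_col(tab$same_set_members)
  pags$sub_members <- split_col(tab$sub_members)
  pags$peptides <- split_col(tab$peptides)
  structure(list(pags = pags, orphaned = character(),
                 min_peptides = NA_integer_), class = "pag_set")
}
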