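# Independent oracles and fixture builders shared across the suite.
# Each oracle deliberately uses different primitives than the package code
# it checks (Biostrings translation, explicit state machines, exhaustive
# enumeration) so that agreement is evidence, not tautology.

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_protein <- function(n) {
  paste(sample(setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z")), n,
               replace = TRUE), collapse = "")
}

bs_revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

bs_translate_frame <- function(s) {
  strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(s), if.fuzzy.codon = "X",
    no.init.codon = TRUE)), "")[[1]]
}

# Six-frame ORF oracle: Biostrings translation per frame, explicit
# state-machine run extraction, then the same declared keep rules.
oracle_find_orfs <- function(seq, min_aa = 20L,
                             mode = "per-frame-longest",
                             require_start = FALSE, allow_partial = TRUE) {
  seq <- toupper(seq)
  L <- nchar(seq)
  rc <- bs_revcomp(seq)
  rows <- list()
  for (fr in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    src <- if (fr > 0) seq else rc
    off <- abs(fr) - 1L
    ncod <- (L - off) %/% 3L
    if (ncod < 1L) next
    aas <- bs_translate_frame(substr(src, off + 1L, off + 3L * ncod))
    codon_at <- function(i) substr(src, off + 3L * (i - 1L) + 1L,
                                   off + 3L * i)
    start <- NULL
    for (i in seq_len(ncod + 1L)) {
      at_stop <- i > ncod || aas[i] == "*"
      if (!at_stop && is.null(start)) start <- i
      if (at_stop && !is.null(start)) {
        i0 <- start; i1 <- i - 1L
        partial5 <- i0 == 1L
        partial3 <- i > ncod
        keep <- TRUE
        if (require_start) {
          atg <- Filter(function(k) codon_at(k) == "ATG", i0:i1)
          if (!length(atg)) keep <- FALSE
          else { i0 <- atg[[1]]; partial5 <- FALSE }
        }
        if (keep && !allow_partial && (partial5 || partial3)) keep <- FALSE
        if (keep) {
          aa <- paste(aas[i0:i1], collapse = "")
          if (2L * sum(strsplit(aa, "")[[1]] == "X") > nchar(aa))
            keep <- FALSE
          if (keep) {
            a <- off + 3L * (i0 - 1L); b <- off + 3L * i1
            rows[[length(rows) + 1L]] <- data.frame(
              frame = fr,
              nt_start = if (fr > 0) a else L - b,
              nt_end = if (fr > 0) b else L - a,
              aa = aa, partial5 = partial5, partial3 = partial3,
              stringsAsFactors = FALSE)
          }
        }
        start <- NULL
      }
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out <- out[nchar(out$aa) >= min_aa, , drop = FALSE]
  if (mode == "per-frame-longest" && nrow(out)) {
    out <- do.call(rbind, lapply(split(out, out$frame), function(d) {
      d[order(-nchar(d$aa), d$nt_start)[1L], , drop = FALSE]
    }))
  }
  if (!nrow(out)) return(NULL)
  out <- out[order(out$nt_start, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exhaustive start/stop-pair ORF oracle for tiny transcripts
# (require_start = FALSE): every codon pair (i, j) is tested for stop
# freedom and maximality directly.
exhaustive_orfs <- function(seq, min_aa, allow_partial = TRUE) {
  seq <- toupper(seq)
  L <- nchar(seq)
  rc <- bs_revcomp(seq)
  rows <- list()
  for (fr in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    src <- if (fr > 0) seq else rc
    off <- abs(fr) - 1L
    ncod <- (L - off) %/% 3L
    if (ncod < 1L) next
    aas <- bs_translate_frame(substr(src, off + 1L, off + 3L * ncod))
    for (i in seq_len(ncod)) for (j in i:ncod) {
      if (any(aas[i:j] == "*")) next
      left_max <- i == 1L || aas[i - 1L] == "*"
      right_max <- j == ncod || aas[j + 1L] == "*"
      if (!left_max || !right_max) next
      partial5 <- i == 1L
      partial3 <- j == ncod
      if (!allow_partial && (partial5 || partial3)) next
      aa <- paste(aas[i:j], collapse = "")
      if (2L * sum(strsplit(aa, "")[[1]] == "X") > nchar(aa)) next
      if (nchar(aa) < min_aa) next
      a <- off + 3L * (i - 1L); b <- off + 3L * j
      rows[[length(rows) + 1L]] <- data.frame(
        frame = fr, nt_start = if (fr > 0) a else L - b,
        nt_end = if (fr > 0) b else L - a, aa = aa,
        partial5 = partial5, partial3 = partial3, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out <- out[order(out$nt_start, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

orf_cols <- c("frame", "nt_start", "nt_end", "aa", "partial5", "partial3")

# Brute-force tryptic digest oracle: every substring, boundary rules
# checked directly.
oracle_digest <- function(protein, missed_cleavages, min_len, max_len) {
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  is_site <- function(k) k >= 1 && k < n && aa[k] %in% c("K", "R") &&
    aa[k + 1L] != "P"
  peps <- character()
  for (i in seq_len(n)) for (j in i:n) {
    if (!(i == 1L || is_site(i - 1L))) next
    if (!(j == n || is_site(j))) next
    internal <- if (j > i) sum(vapply(i:(j - 1L), is_site, logical(1)))
                else 0L
    if (internal > missed_cleavages) next
    len <- j - i + 1L
    if (len < min_len || len > max_len) next
    peps <- c(peps, paste(aa[i:j], collapse = ""))
  }
  unique(peps)
}

# Brute-force all-pairs substring mapping oracle.
oracle_map <- function(peptides, db) {
  rows <- list()
  for (p in unique(peptides)) for (i in seq_len(nrow(db))) {
    s <- db$sequence[i]
    for (k in seq_len(nchar(s) - nchar(p) + 1L)) {
      if (substr(s, k, k + nchar(p) - 1L) == p)
        rows[[length(rows) + 1L]] <- data.frame(
          peptide = p, protein_id = db$id[i], start = k - 1L,
          end = k - 1L + nchar(p), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out[order(out$peptide, out$protein_id, out$start), , drop = FALSE]
}

# Independent grouping oracle (setequal/subset primitives, explicit scan).
oracle_group <- function(sets, min_peptides = 2L) {
  prots <- names(sets)
  ord <- prots[order(-vapply(sets, length, integer(1)), prots)]
  groups <- list()
  for (p in ord) {
    placed <- FALSE
    for (gi in seq_along(groups)) {
      if (setequal(sets[[p]], groups[[gi]]$aset)) {
        groups[[gi]]$same <- c(groups[[gi]]$same, p); placed <- TRUE; break
      }
    }
    if (!placed) for (gi in seq_along(groups)) {
      if (length(sets[[p]]) < length(groups[[gi]]$aset) &&
          all(sets[[p]] %in% groups[[gi]]$aset)) {
        groups[[gi]]$sub <- c(groups[[gi]]$sub, p); placed <- TRUE; break
      }
    }
    if (!placed)
      groups[[length(groups) + 1L]] <- list(anchor = p, aset = sets[[p]],
                                            same = character(),
                                            sub = character())
  }
  groups[vapply(groups, function(g) length(g$aset) >= min_peptides,
                logical(1))]
}

# Greedy one-use PAG matcher oracle: repeated global argmin extraction.
oracle_match_totals <- function(pags_a, pags_b, hits, thr) {
  pa <- pags_a$pags; pb <- pags_b$pags
  members <- function(p, i) unique(c(p$anchor[i], p$same_set[[i]],
                                     p$sub_members[[i]]))
  own_a <- lapply(seq_len(nrow(pa)), function(i) members(pa, i))
  own_b <- lapply(seq_len(nrow(pb)), function(i) members(pb, i))
  locate <- function(acc, own) {
    for (i in seq_along(own)) if (acc %in% own[[i]]) return(i)
    NA_integer_
  }
  h <- hits[hits$evalue < thr, , drop = FALSE]
  if (!nrow(h))
    return(list(anchor_anchor = 0L, anchor_submember = 0L,
                unmatched_a = nrow(pa), unmatched_b = nrow(pb)))
  h$ia <- vapply(h$query_id, locate, integer(1), own = own_a)
  h$ib <- vapply(h$subject_id, locate, integer(1), own = own_b)
  h <- h[!is.na(h$ia) & !is.na(h$ib), , drop = FALSE]
  used_a <- logical(nrow(pa)); used_b <- logical(nrow(pb))
  totals <- c(0L, 0L)
  for (pass in 1:2) {
    repeat {
      cand <- which(!used_a[h$ia] & !used_b[h$ib])
      if (pass == 1) {
        cand <- cand[h$query_id[cand] == pa$anchor[h$ia[cand]] &
                       h$subject_id[cand] == pb$anchor[h$ib[cand]]]
      } else {
        cand <- cand[xor(h$query_id[cand] == pa$anchor[h$ia[cand]],
                         h$subject_id[cand] == pb$anchor[h$ib[cand]])]
      }
      if (!length(cand)) break
      best <- cand[order(h$evalue[cand],
                         pmin(h$query_id[cand], h$subject_id[cand]),
                         pmax(h$query_id[cand], h$subject_id[cand]))][1L]
      used_a[h$ia[best]] <- TRUE; used_b[h$ib[best]] <- TRUE
      totals[pass] <- totals[pass] + 1L
    }
  }
  list(anchor_anchor = totals[1], anchor_submember = totals[2],
       unmatched_a = sum(!used_a), unmatched_b = sum(!used_b))
}

# Small evidence frame from per-protein peptide sets.
evidence_from_sets <- function(sets) {
  do.call(rbind, lapply(names(sets), function(p) {
    if (!length(sets[[p]])) return(NULL)
    data.frame(peptide_key = sets[[p]], peptide = sets[[p]], protein_id = p,
               start = 0L, end = nchar(sets[[p]]), stringsAsFactors = FALSE)
  }))
}

# Splice-aware extraction of a peptide feature's coding sequence from a
# genome record frame, then translation — the projection round-trip oracle.
roundtrip_peptide <- function(gp, genome) {
  gs <- genome$sequence[match(gp$seqid, genome$id)]
  pieces <- substring(gs, gp$segments[, "start"] + 1L, gp$segments[, "end"])
  fwd <- paste(pieces, collapse = "")
  cod <- if (gp$strand == "-") bs_revcomp(fwd) else fwd
  as.character(Biostrings::translate(Biostrings::DNAString(cod),
                                     if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}
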