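#' Parameters for the synthetic scene generator
#'
#' Defaults describe a small but structurally complete study: 50 spliced
#' genes on two chromosomes, half on the reverse strand, each transcript
#' carrying one ATG-initiated stop-terminated ORF of 60-150 codons flanked
#' by short UTRs, and scored target/decoy PSMs whose correct matches are
#' drawn from a Gaussian well separated from the incorrect/decoy Gaussian
#' with 10% of target PSMs incorrect — the statistical structure that
#' target-decoy FDR estimation assumes.
#'
#' @param seed Integer seed; all randomness flows from it.
#' @param n_genes Number of genes (default 50).
#' @param exons_per_gene Integer range (default 1-4).
#' @param exon_len Exon length range in nt (default 60-240).
#' @param intron_len Intron length range in nt (default 60-200).
#' @param frac_reverse_strand Proportion of genes on `-` (default 0.5).
#' @param orf_aa ORF length range in codons (default 60-150).
#' @param n_true_peptides_per_orf Planted peptides per ORF (default 3).
#' @param n_psms Total target PSMs for [simulate_psms()] (default 10000).
#' @param score_true,score_false `(mean, sd)` of correct and
#'   incorrect/decoy match scores (defaults `c(25, 4)` and `c(12, 4)`).
#' @param frac_false_targets Proportion of target PSMs drawn from the
#'   incorrect-score distribution (default 0.10).
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(seed = 1L, n_genes = 50L, exons_per_gene = c(1L, 4L),
                       exon_len = c(60L, 240L), intron_len = c(60L, 200L),
                       frac_reverse_strand = 0.5, orf_aa = c(60L, 150L),
                       n_true_peptides_per_orf = 3L, n_psms = 10000L,
                       score_true = c(25, 4), score_false = c(12, 4),
                       frac_false_targets = 0.10) {
  p <- list(seed = as.integer(seed), n_genes = n_genes,
            exons_per_gene = exons_per_gene, exon_len = exon_len,
            intron_len = intron_len,
            frac_reverse_strand = frac_reverse_strand, orf_aa = orf_aa,
            n_true_peptides_per_orf = n_true_peptides_per_orf,
            n_psms = n_psms, score_true = score_true,
            score_false = score_false,
            frac_false_targets = frac_false_targets)
  ranges <- list(p$exons_per_gene, p$exon_len, p$intron_len, p$orf_aa)
  if (any(vapply(ranges, function(r) r[1] > r[2] || r[1] < 1, logical(1))))
    stop("unsatisfiable range parameter")
  if (p$frac_reverse_strand < 0 || p$frac_reverse_strand > 1 ||
      p$frac_false_targets < 0 || p$frac_false_targets > 1)
    stop("proportions must lie in [0, 1]")
  class(p) <- "sim_params"
  p
}

SENSE_CODONS <- setdiff(
  apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                    c("A","C","G","T")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

rand_dna <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                              collapse = "")

rint <- function(range) if (range[1] == range[2]) range[1] else
  sample(range[1]:range[2], 1L)

# Builds one transcript with a planted ORF: 5' UTR whose in-frame codon
# immediately before the ATG is a stop (so the planted ORF is exactly a
# maximal stop-free run), a coding region free of internal stops, a stop
# codon, and a 3' UTR.
plant_transcript <- function(params) {
  n_aa <- rint(params$orf_aa)
  utr5_pad <- rint(c(6L, 30L))
  utr5 <- paste0(rand_dna(utr5_pad), "TAA")
  coding <- paste(c("ATG", sample(SENSE_CODONS, n_aa - 1L, replace = TRUE)),
                  collapse = "")
  utr3 <- rand_dna(rint(c(10L, 40L)))
  seq <- paste0(utr5, coding, "TGA", utr3)
  nt_start <- nchar(utr5)
  list(sequence = seq, nt_start = nt_start, nt_end = nt_start + 3L * n_aa,
       frame = (nt_start %% 3L) + 1L, aa = translate(coding))
}

# Independent per-base coordinate mapper used to record ground-truth genome
# segments (deliberately not the interval projection used by the package's
# own integration code).
truth_segments <- function(blocks, strand, t_lo, t_hi) {
  gpos <- vapply(t_lo:(t_hi - 1L), function(tp) {
    k <- which(blocks[, "t_start"] <= tp & tp < blocks[, "t_end"])
    if (strand == "+") blocks[k, "g_start"] + (tp - blocks[k, "t_start"])
    else blocks[k, "g_end"] - 1L - (tp - blocks[k, "t_start"])
  }, numeric(1))
  gpos <- sort(as.integer(gpos))
  brk <- c(0L, which(diff(gpos) != 1L), length(gpos))
  segs <- cbind(start = gpos[brk[-length(brk)] + 1L],
                end = gpos[brk[-1L]] + 1L)
  segs
}

#' Simulate a genome scene with spliced genes and known ground truth
#'
#' Generates a random genome on two chromosomes, spliced gene models on
#' both strands, transcripts that are exact spliced extracts of the genome,
#' alignments encoding the true exon blocks, and per-gene planted ORFs with
#' planted tryptic peptides whose genome segments are recorded by an
#' independent per-base mapper.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `sim_scene`: `genome`, `transcripts` (FASTA
#'   frames), `alignments` (named list of [transcript_alignment()]),
#'   `truth` (per-transcript list: blocks, strand, seqid, orf coordinates,
#'   planted peptides with genome segments), `params`.
#' @export
simulate_scene <- function(params = sim_params()) {
  set.seed(params$seed)
  n_chr <- 2L
  chrom <- paste0("chr", seq_len(n_chr))
  chr_parts <- stats::setNames(vector("list", n_chr), chrom)
  chr_len <- stats::setNames(integer(n_chr), chrom)
  transcripts <- list(); alignments <- list(); truth <- list()
  for (g in seq_len(params$n_genes)) {
    tid <- sprintf("tr%03d", g)
    tr <- plant_transcript(params)
    tlen <- nchar(tr$sequence)
    n_ex <- min(rint(params$exons_per_gene), max(1L, tlen %/% 30L))
    # cut the transcript into n_ex chunks, each >= 15 nt
    if (n_ex > 1L) {
      cuts <- sort(sample(seq(15L, tlen - 15L), n_ex - 1L))
      while (any(diff(c(0L, cuts, tlen)) < 15L)) {
        cuts <- sort(sample(seq(15L, tlen - 15L), n_ex - 1L))
      }
    } else cuts <- integer()
    t_bounds <- c(0L, cuts, tlen)
    chunks <- substring(tr$sequence, t_bounds[-length(t_bounds)] + 1L,
                        t_bounds[-1L])
    strand <- if (stats::runif(1) < params$frac_reverse_strand) "-" else "+"
    seqid <- chrom[(g %% n_chr) + 1L]
    offset <- chr_len[seqid] + rint(c(40L, 120L))
    # genomic order of chunks: forward order on +, reversed on -
    genome_chunks <- if (strand == "+") chunks else
      rev(reverse_complement(chunks))
    g_start <- integer(n_ex); g_end <- integer(n_ex)
    pieces <- character()
    pos <- offset
    for (i in seq_len(n_ex)) {
      if (i > 1L) {
        ilen <- rint(params$intron_len)
        pieces <- c(pieces, rand_dna(ilen))
        pos <- pos + ilen
      }
      g_start[i] <- pos
      pieces <- c(pieces, genome_chunks[i])
      pos <- pos + nchar(genome_chunks[i])
      g_end[i] <- pos
    }
    chr_parts[[seqid]] <- c(chr_parts[[seqid]],
                            rand_dna(offset - chr_len[seqid]), pieces)
    chr_len[seqid] <- pos
    # blocks in transcript order
    if (strand == "+") {
      blocks <- cbind(t_bounds[-length(t_bounds)], t_bounds[-1L],
                      g_start, g_end)
    } else {
      # chunk i of the transcript sits at genomic position n_ex - i + 1
      idx <- rev(seq_len(n_ex))
      blocks <- cbind(t_bounds[-length(t_bounds)], t_bounds[-1L],
                      g_start[idx], g_end[idx])
    }
    aln <- transcript_alignment(tid, seqid, strand, blocks)
    peps <- tryptic_digest(tr$aa, missed_cleavages = 0L, min_len = 7L,
                           max_len = 30L)
    n_pick <- min(params$n_true_peptides_per_orf, length(peps))
    picked <- if (n_pick) sample(peps, n_pick) else character()
    pep_truth <- lapply(picked, function(pp) {
      off <- as.integer(regexpr(pp, tr$aa, fixed = TRUE)) - 1L
      t_lo <- tr$nt_start + 3L * off
      t_hi <- t_lo + 3L * nchar(pp)
      list(peptide = pp, protein_start = off,
           segments = truth_segments(aln$blocks, strand, t_lo, t_hi),
           strand = if (strand == "+") "+" else "-")
    })
    transcripts[[tid]] <- tr$sequence
    alignments[[tid]] <- aln
    truth[[tid]] <- list(seqid = seqid, strand = strand, blocks = aln$blocks,
                         orf = tr[c("nt_start", "nt_end", "frame", "aa")],
                         peptides = pep_truth)
  }
  genome <- fasta_records(
    id = chrom,
    sequence = vapply(chrom, function(cn) {
      paste(c(chr_parts[[cn]], rand_dna(50L)), collapse = "")
    }, character(1)),
    description = "synthetic chromosome")
  structure(list(
    genome = genome,
    transcripts = fasta_records(id = names(transcripts),
                                sequence = unlist(transcripts),
                                description = "synthetic transcript"),
    alignments = alignments, truth = truth, params = params),
    class = "sim_scene")
}

#' @export
print.sim_scene <- function(x, ...) {
  cat("Synthetic scene:", nrow(x$transcripts), "transcript(s) on",
      nrow(x$genome), "chromosome(s), seed", x$params$seed, "\n")
  invisible(x)
}

#' Write a simulated scene to disk
#'
#' Writes `genome.fa`, `transcripts.fa`, `alignments.gff3` (mRNA + exon
#' features, the dialect read back by [read_transcript_alignments()]) and
#' `truth.json`.
#'
#' @param scene A `sim_scene` from [simulate_scene()].
#' @param dir Output directory (created if needed).
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(scene$genome, file.path(dir, "genome.fa"))
  write_fasta(scene$transcripts, file.path(dir, "transcripts.fa"))
  feats <- list()
  for (tid in names(scene$alignments)) {
    aln <- scene$alignments[[tid]]
    b <- aln$blocks
    feats[[length(feats) + 1L]] <- gff3_features(
      aln$seqid, "synthfix", "mRNA", min(b[, "g_start"]) + 1L,
      max(b[, "g_end"]), strand = aln$strand,
      attributes = list(c(ID = tid)))
    go <- order(b[, "g_start"])
    feats[[length(feats) + 1L]] <- gff3_features(
      aln$seqid, "synthfix", "exon", b[go, "g_start"] + 1L, b[go, "g_end"],
      strand = aln$strand,
      attributes = lapply(seq_along(go), function(i)
        c(ID = paste0(tid, ".exon", i), Parent = tid)))
  }
  write_gff3(do.call(rbind, feats), file.path(dir, "alignments.gff3"))
  truth <- lapply(scene$truth, function(tt) {
    tt$blocks <- apply(tt$blocks, 1, as.list)
    tt$peptides <- lapply(tt$peptides, function(p) {
      p$segments <- apply(p$segments, 1, as.list)
      p
    })
    tt
  })
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Simulate scored target/decoy PSMs with truth labels
#'
#' Correct PSMs sample peptides from the tryptic digest of the target
#' entries; incorrect target PSMs sample from a disjoint slice of the same
#' digest; decoy PSMs sample from the decoy entries' digest. Correct scores
#' are drawn from `Normal(score_true)`, incorrect and decoy scores from
#' `Normal(score_false)`. The number of decoy PSMs equals the number of
#' incorrect target PSMs, the regime in which the decoy count calibrates
#' the false-target count.
#'
#' @param orf_db_with_decoys FASTA frame containing targets and
#'   `DECOY_`-prefixed decoys ([generate_decoy_database()]).
#' @param params A [sim_params()] object (uses `n_psms`,
#'   `frac_false_targets`, `score_true`, `score_false`, `seed`).
#' @param seed Optional seed overriding `params$seed`.
#' @param decoy_prefix Decoy accession prefix.
#' @return A list: `psms` (PSM frame as from [read_psm_table()]), `labels`
#'   (`data.frame` with `spectrum_id`, `peptide`, `label` in
#'   `{"true","false","decoy"}`), `true_peptides`, `false_peptides`.
#' @export
simulate_psms <- function(orf_db_with_decoys, params = sim_params(),
                          seed = NULL, decoy_prefix = "DECOY_") {
  if (!nrow(orf_db_with_decoys)) stop("empty database")
  set.seed(if (is.null(seed)) params$seed else seed)
  is_dec <- startsWith(orf_db_with_decoys$id, decoy_prefix)
  targets <- orf_db_with_decoys[!is_dec, , drop = FALSE]
  decoys <- orf_db_with_decoys[is_dec, , drop = FALSE]
  if (!nrow(targets) || !nrow(decoys))
    stop("database must contain both targets and decoys")
  pep2prot <- function(db) {
    pp <- lapply(db$sequence, tryptic_digest, missed_cleavages = 1L,
                 min_len = 7L, max_len = 30L)
    data.frame(peptide = unlist(pp, use.names = FALSE),
               protein = rep(db$id, lengths(pp)), stringsAsFactors = FALSE)
  }
  tgt <- pep2prot(targets)
  tgt <- tgt[!duplicated(tgt$peptide), , drop = FALSE]
  dcy <- pep2prot(decoys)
  dcy <- dcy[!duplicated(dcy$peptide) & !dcy$peptide %in% tgt$peptide, ,
             drop = FALSE]
  # disjoint true/false target peptide pools
  n_false_pool <- max(1L, round(0.2 * nrow(tgt)))
  false_idx <- sample(nrow(tgt), n_false_pool)
  pool_false <- tgt[false_idx, , drop = FALSE]
  pool_true <- tgt[-false_idx, , drop = FALSE]
  n <- params$n_psms
  n_false <- round(params$frac_false_targets * n)
  n_true <- n - n_false
  draw <- function(pool, k) pool[sample(nrow(pool), k, replace = TRUE), ,
                                 drop = FALSE]
  dt <- draw(pool_true, n_true)
  df <- draw(pool_false, n_false)
  dd <- draw(dcy, n_false)
  score <- c(stats::rnorm(n_true, params$score_true[1], params$score_true[2]),
             stats::rnorm(2L * n_false, params$score_false[1],
                          params$score_false[2]))
  psms <- data.frame(
    spectrum_id = sprintf("scan%06d", seq_len(n_true + 2L * n_false)),
    peptide = c(dt$peptide, df$peptide, dd$peptide),
    modifications = "",
    score = round(score, 4),
    proteins = c(dt$protein, df$protein, dd$protein),
    is_decoy = rep(c(FALSE, FALSE, TRUE), c(n_true, n_false, n_false)),
    stringsAsFactors = FALSE)
  labels <- data.frame(
    spectrum_id = psms$spectrum_id, peptide = psms$peptide,
    label = rep(c("true", "false", "decoy"), c(n_true, n_false, n_false)),
    stringsAsFactors = FALSE)
  list(psms = psms, labels = labels,
       true_peptides = unique(dt$peptide),
       false_peptides = unique(df$peptide))
}

#' Simulate homology hits between two PAG lists
#'
#' Anchors are truth-paired in order; each true pair receives an e-value
#' strictly below the threshold, and a configurable number of distractor
#' hits between non-paired accessions receive e-values above it.
#'
#' @param pags_a,pags_b `pag_set` objects.
#' @param seed Integer seed.
#' @param evalue_threshold Threshold the truth pairs must beat (default
#'   `1e-30`).
#' @param n_ambiguous Number of distractor hits (default
#'   `round(0.2 * pairs)`).
#' @return List with `hits` (BLAST tabular frame) and `truth_pairs`
#'   (`data.frame` `pag_a`, `pag_b`).
#' @export
simulate_homology <- function(pags_a, pags_b, seed = 1L,
                              evalue_threshold = 1e-30,
                              n_ambiguous = NULL) {
  set.seed(seed)
  pa <- pags_a$pags; pb <- pags_b$pags
  k <- min(nrow(pa), nrow(pb))
  if (is.null(n_ambiguous)) n_ambiguous <- round(0.2 * k)
  mk_hit <- function(q, s, ev) data.frame(
    query_id = q, subject_id = s, pct_identity = round(stats::runif(1, 90, 100), 1),
    aln_length = sample(50:400, 1L), mismatches = sample(0:5, 1L),
    gap_opens = 0L, q_start = 1L, q_end = 50L, s_start = 1L, s_end = 50L,
    evalue = ev, bitscore = round(stats::runif(1, 100, 500), 1), extra = "",
    stringsAsFactors = FALSE)
  hits <- list()
  for (i in seq_len(k)) {
    ev <- 10^-stats::runif(1, -log10(evalue_threshold) + 1, 60)
    hits[[length(hits) + 1L]] <- mk_hit(pa$anchor[i], pb$anchor[i], ev)
  }
  if (n_ambiguous > 0 && k > 1) {
    for (j in seq_len(n_ambiguous)) {
      ia <- sample(k, 1L); ib <- sample(setdiff(seq_len(k), ia), 1L)
      ev <- 10^-stats::runif(1, 2, -log10(evalue_threshold) - 1)
      hits[[length(hits) + 1L]] <- mk_hit(pa$anchor[ia], pb$anchor[ib], ev)
    }
  }
  list(hits = do.call(rbind, c(list(blast_empty()), hits)),
       truth_pairs = data.frame(pag_a = pa$pag_id[seq_len(k)],
                                pag_b = pb$pag_id[seq_len(k)],
                                stringsAsFactors = FALSE))
}
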