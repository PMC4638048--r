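test_that("tryptic digestion cleaves after K/R except before P", {
  expect_setequal(tryptic_digest("MKRAP", 0, min_len = 1, max_len = Inf),
                  c("MK", "R", "AP"))
  expect_setequal(tryptic_digest("MKPR", 0, min_len = 1, max_len = Inf),
                  "MKPR")
  expect_setequal(tryptic_digest("MKRAP", 1, min_len = 1, max_len = Inf),
                  c("MK", "R", "AP", "MKR", "RAP"))
  expect_equal(tryptic_digest("", 0), character())
})

test_that("digestion agrees with a brute-force boundary-rule oracle", {
  set.seed(91)
  for (i in 1:100) {
    prot <- random_protein(sample(10:80, 1))
    mc <- sample(0:3, 1)
    lo <- sample(1:5, 1); hi <- sample(10:60, 1)
    expect_setequal(tryptic_digest(prot, mc, lo, hi),
                    oracle_digest(prot, mc, lo, hi))
  }
})

test_that("peptide overlap reports satisfy conservation and symmetry", {
  set.seed(93)
  shared <- replicate(300, random_protein(10))
  only_a <- replicate(80, random_protein(11))
  only_b <- replicate(40, random_protein(12))
  rep_ab <- compare_peptides(c(shared, only_a), c(shared, only_b))
  expect_equal(rep_ab$n_a, rep_ab$shared + rep_ab$unique_a)
  expect_equal(rep_ab$n_b, rep_ab$shared + rep_ab$unique_b)
  rep_ba <- compare_peptides(c(shared, only_b), c(shared, only_a))
  expect_equal(rep_ab$overlap_pct, rep_ba$overlap_pct)
  expect_equal(rep_ab$overlap_pct,
               as.integer(round(100 * 300 / (300 + 80 + 40))))
  # identical sets and empty lists are degenerate but defined
  same <- compare_peptides(shared, shared)
  expect_equal(same$overlap_pct, 100L)
  expect_equal(same$unique_a + same$unique_b, 0L)
  none <- compare_peptides(character(), character())
  expect_equal(none$overlap_pct, 0L)
  expect_equal(none$n_a, 0L)
})

test_that("database-absence attribution uses the opposing digest universe", {
  db_a <- fasta_records("A1", "MAAAAAAKEEEEEEER")
  db_b <- fasta_records("B1", "MAAAAAAKDDDDDDDR")
  # retained_a's unique peptide EEEEEEER is absent from db_b's digest
  rep <- compare_peptides(c("MAAAAAAK", "EEEEEEER"),
                          c("MAAAAAAK", "DDDDDDDR"),
                          db_a = db_a, db_b = db_b, missed_cleavages = 0,
                          min_len = 1, max_len = Inf)
  expect_equal(rep$absent_from_other_db_a, 1L)
  expect_equal(rep$absent_pct_a, 100.0)
  expect_equal(rep$absent_from_other_db_b, 1L)
  # printed-count helpers reproduce table arithmetic at one decimal
  expect_equal(attribution_percent(813, 1389), 58.5)
  expect_equal(attribution_percent(0, 0), NA_real_)
})

test_that("PAG matching is greedy, one use per PAG, strict threshold", {
  mk_pags <- function(anchors, subs = NULL) {
    pags <- data.frame(pag_id = paste0("G", seq_along(anchors), "_", anchors),
                       anchor = anchors, n_peptides = 3L,
                       stringsAsFactors = FALSE)
    pags$same_set <- rep(list(character()), length(anchors))
    pags$sub_members <- if (is.null(subs)) rep(list(character()),
                                               length(anchors)) else subs
    pags$peptides <- rep(list(c("x", "y", "z")), length(anchors))
    structure(list(pags = pags, orphaned = character(), min_peptides = 2L),
              class = "pag_set")
  }
  pa <- mk_pags(c("A1", "A2"))
  pb <- mk_pags(c("B1", "B2"), subs = list(character(), "B2sub"))
  hit <- function(q, s, ev) data.frame(
    query_id = q, subject_id = s, pct_identity = 99, aln_length = 50,
    mismatches = 0L, gap_opens = 0L, q_start = 1L, q_end = 50L,
    s_start = 1L, s_end = 50L, evalue = ev, bitscore = 200, extra = "",
    stringsAsFactors = FALSE)
  # anchor-anchor match below threshold
  rep1 <- match_pags(pa, pb, hit("A1", "B1", 1e-40))
  expect_equal(rep1$anchor_anchor, 1L)
  expect_equal(rep1$total_matches, 1L)
  # e-value above threshold: no match
  expect_equal(match_pags(pa, pb, hit("A1", "B1", 1e-20))$total_matches, 0L)
  # anchor-submember goes to pass 2
  rep2 <- match_pags(pa, pb, hit("A2", "B2sub", 1e-45))
  expect_equal(rep2$anchor_anchor, 0L)
  expect_equal(rep2$anchor_submember, 1L)
  # one use per PAG: two hits to the same B PAG yield one match
  rep3 <- match_pags(pa, pb, rbind(hit("A1", "B1", 1e-40),
                                   hit("A2", "B1", 1e-50)))
  expect_equal(rep3$total_matches, 1L)
  expect_equal(rep3$matches$pag_a, "G2_A2")   # lower e-value wins
  # unknown accessions are ignored with a diagnostic
  rep4 <- match_pags(pa, pb, hit("NOPE", "B1", 1e-40))
  expect_equal(rep4$total_matches, 0L)
  expect_equal(attr(rep4, "ignored_hits"), 1L)
})

test_that("strict-inequality boundary at the e-value threshold", {
  pa <- group_proteins(evidence_from_sets(list(A1 = c("p1", "p2"))))
  pb <- group_proteins(evidence_from_sets(list(B1 = c("q1", "q2"))))
  hit <- function(ev) data.frame(
    query_id = "A1", subject_id = "B1", pct_identity = 99, aln_length = 50,
    mismatches = 0L, gap_opens = 0L, q_start = 1L, q_end = 50L,
    s_start = 1L, s_end = 50L, evalue = ev, bitscore = 200, extra = "",
    stringsAsFactors = FALSE)
  expect_equal(match_pags(pa, pb, hit(1e-30))$total_matches, 0L)
  expect_equal(match_pags(pa, pb, hit(1e-31))$total_matches, 1L)
})

test_that("greedy matching equals the exhaustive one-use matcher on random instances", {
  set.seed(97)
  for (trial in 1:30) {
    na <- sample(2:10, 1); nb <- sample(2:10, 1)
    mk <- function(n, side) {
      pags <- data.frame(pag_id = sprintf("%s%02d", side, 1:n),
                         anchor = sprintf("%sacc%02d", side, 1:n),
                         n_peptides = 2L, stringsAsFactors = FALSE)
      pags$same_set <- rep(list(character()), n)
      pags$sub_members <- lapply(1:n, function(i)
        if (runif(1) < 0.4) sprintf("%ssub%02d", side, i) else character())
      pags$peptides <- rep(list(c("x", "y")), n)
      structure(list(pags = pags, orphaned = character(),
                     min_peptides = 2L), class = "pag_set")
    }
    pa <- mk(na, "A"); pb <- mk(nb, "B")
    accs_a <- unlist(pitkit:::pag_members(pa$pags))
    accs_b <- unlist(pitkit:::pag_members(pb$pags))
    n_hits <- sample(5:25, 1)
    hits <- data.frame(
      query_id = sample(accs_a, n_hits, replace = TRUE),
      subject_id = sample(accs_b, n_hits, replace = TRUE),
      pct_identity = 99, aln_length = 50, mismatches = 0L, gap_opens = 0L,
      q_start = 1L, q_end = 50L, s_start = 1L, s_end = 50L,
      evalue = 10^-sample(10:60, n_hits, replace = TRUE), bitscore = 200,
      extra = "", stringsAsFactors = FALSE)
    got <- match_pags(pa, pb, hits)
    want <- oracle_match_totals(pa, pb, hits, 1e-30)
    expect_equal(got$anchor_anchor, want$anchor_anchor)
    expect_equal(got$anchor_submember, want$anchor_submember)
    expect_equal(length(got$unmatched_a), want$unmatched_a)
    expect_equal(length(got$unmatched_b), want$unmatched_b)
    # label-swap symmetry of totals
    swapped <- hits
    names(swapped)[1:2] <- c("subject_id", "query_id")
    got_ba <- match_pags(pb, pa, swapped)
    expect_equal(got_ba$total_matches, got$total_matches)
  }
})

test_that("unmatched PAGs are classified by the decision cascade with planted categories", {
  sets <- list(A1 = c("p1", "p2"), A2 = c("p3", "p4"), A3 = c("p5", "p6"),
               A4 = c("p7", "p8"), A5 = c("p9", "p10"), A6 = c("p11", "p12"),
               A7 = c("p13", "p14"))
  pa <- group_proteins(evidence_from_sets(sets))
  pags <- pa$pags
  # A1 matched; A2 shares a member with A1's group via sub_members
  pags$sub_members[[which(pags$anchor == "A2")]] <- "A1"
  pa$pags <- pags
  matched <- pags$pag_id[pags$anchor == "A1"]
  unmatched <- setdiff(pags$pag_id, matched)
  cls <- classify_unmatched(
    unmatched, pa, matched,
    transcript_support = c(A2 = TRUE, A3 = FALSE, A4 = TRUE, A5 = TRUE,
                           A6 = TRUE, A7 = TRUE),
    surviving_orfs = c("A2", "A5", "A6", "A7"),
    other_search_peptide_counts = c(A5 = 1L, A6 = 5L),
    orf_db = fasta_records(c("A6", "A7"),
                           c("MAAAPEPTIDEKBBBB", "MCCCCCC")),
    reference_db = fasta_records("R1", "PEPTIDEK"),
    evidence = data.frame(peptide = c("MAAA", "TIDEK"),
                          protein_id = c("A6", "A6"),
                          start = c(0L, 7L), end = c(4L, 12L),
                          stringsAsFactors = FALSE))
  got <- structure(cls$category,
                   names = pags$anchor[match(cls$pag_id, pags$pag_id)])
  expect_equal(unname(got["A2"]), "isoform_of_matched")
  expect_equal(unname(got["A3"]), "no_transcript_evidence")
  expect_equal(unname(got["A4"]), "orf_failure")
  expect_equal(unname(got["A5"]), "single_peptide_in_other_search")
  expect_equal(unname(got["A6"]), "extended_orf")
  expect_equal(unname(got["A7"]), "no_known_homology")
  # exactly one category per PAG; counts conserve
  expect_equal(nrow(cls), length(unmatched))
  expect_equal(sum(table(cls$category)), length(unmatched))
  # missing auxiliary inputs disable categories, never crash
  cls2 <- classify_unmatched(unmatched, pa, matched)
  expect_true("no_transcript_evidence" %in% attr(cls2, "disabled"))
  expect_true(all(cls2$category %in% c("isoform_of_matched",
                                       "no_known_homology")))
})
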