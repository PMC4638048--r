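#' Run the full PIT pipeline on a synthetic scene
#'
#' Chains every stage end to end: scene simulation, six-frame ORF database
#' construction, decoy generation, PSM simulation, peptide-level q-values
#' and filtering, peptide-to-protein mapping, ambiguity grouping, and
#' genome integration. The run report accounts for every peptide: retained
#' peptides are either covered by a surviving ambiguity group, orphaned by
#' the minimum-peptide rule, or listed as unmapped — nothing is silently
#' dropped.
#'
#' @param params A [sim_params()] object.
#' @param fdr_threshold Peptide q-value threshold (default 0.01).
#' @param min_peptides Two-peptide rule cutoff (default 2).
#' @param orf_mode ORF retention mode passed to [build_orf_database()]
#'   (default `"all-above-min"`, so that planted ORFs are searchable even
#'   when a chance ORF in another frame is longer).
#' @param out_dir Optional directory: when given, scene files, the ORF
#'   database, PSM table, peptide and PAG tables and the annotation bundle
#'   are written there.
#' @return A list of class `pit_run` with all intermediate products and a
#'   `report` summarising counts and conservation checks.
#' @export
run_pipeline <- function(params = sim_params(), fdr_threshold = 0.01,
                         min_peptides = 2L, orf_mode = "all-above-min",
                         out_dir = NULL) {
  scene <- simulate_scene(params)
  orfdb <- build_orf_database(scene$transcripts, mode = orf_mode)
  db_td <- generate_decoy_database(orfdb$db)
  sim <- simulate_psms(db_td, params)
  scored <- peptide_level_scores(sim$psms)
  scored <- compute_q_values(scored)
  retained <- filter_peptides(scored, fdr_threshold)
  mapping <- map_peptides_to_proteins(retained, db_td)
  pags <- group_proteins(mapping$evidence, min_peptides = min_peptides)
  bundle <- integrate_annotations(pags, retained, mapping$evidence,
                                  orfdb$index, scene$alignments,
                                  genome = scene$genome)
  covered <- unique(unlist(pags$pags$peptides, use.names = FALSE))
  mapped <- unique(mapping$evidence$peptide)
  report <- list(
    n_transcripts = nrow(scene$transcripts),
    n_orfs = nrow(orfdb$index),
    n_psms = nrow(sim$psms),
    n_peptides = nrow(scored),
    n_retained = nrow(retained),
    n_mapped = length(mapped),
    n_unmapped = length(mapping$unmapped),
    n_pags = nrow(pags$pags),
    n_orphaned = length(pags$orphaned),
    n_peptide_features = bundle$report$n_peptide_features,
    n_unprojectable = bundle$report$n_unprojectable,
    # conservation: every retained peptide is mapped or unmapped, and every
    # mapped peptide is covered by a PAG or orphaned
    conserved = (length(mapped) + length(mapping$unmapped) ==
                   nrow(retained)) &&
      (length(covered) + length(pags$orphaned) == length(mapped)))
  run <- structure(list(scene = scene, orf_db = orfdb$db,
                        orf_index = orfdb$index, db_with_decoys = db_td,
                        psms = sim$psms, labels = sim$labels,
                        peptides = scored, retained = retained,
                        evidence = mapping$evidence,
                        unmapped = mapping$unmapped, pags = pags,
                        bundle = bundle, report = report),
                   class = "pit_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_scene(scene, out_dir)
    write_fasta(orfdb$db, file.path(out_dir, "orfs.fa"))
    write_orf_index(orfdb$index, file.path(out_dir, "orfs.tsv"))
    write_fasta(db_td, file.path(out_dir, "orfs_td.fa"))
    write_psm_table(sim$psms, file.path(out_dir, "psms.tsv"))
    utils::write.table(retained, file.path(out_dir, "peptides.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_pag_table(pags, file.path(out_dir, "pags.tsv"))
    write_annotation_bundle(bundle,
                            gff3 = file.path(out_dir, "annotation.gff3"),
                            sam = file.path(out_dir, "annotation.sam"),
                            table = file.path(out_dir, "annotation.tsv"))
  }
  run
}

#' @export
print.pit_run <- function(x, ...) {
  r <- x$report
  cat("PIT pipeline run (seed ", x$scene$params$seed, ")\n", sep = "")
  cat("  transcripts: ", r$n_transcripts, ", ORFs: ", r$n_orfs,
      ", PSMs: ", r$n_psms, "\n", sep = "")
  cat("  peptides: ", r$n_peptides, " scored, ", r$n_retained,
      " retained at q <= threshold\n", sep = "")
  cat("  mapped: ", r$n_mapped, " (", r$n_unmapped, " unmapped), PAGs: ",
      r$n_pags, " (", r$n_orphaned, " peptide(s) orphaned)\n", sep = "")
  cat("  peptide features: ", r$n_peptide_features, " (",
      r$n_unprojectable, " unprojectable)\n", sep = "")
  cat("  evidence conserved:", r$conserved, "\n")
  invisible(x)
}
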