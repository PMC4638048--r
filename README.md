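# pitkit

Proteogenomic identification with sample-specific databases: six-frame ORF
databases from assembled transcripts, target-decoy peptide FDR, protein
ambiguity grouping, and peptide-to-genome annotation.

## The problem

Shotgun proteomics identifies proteins by searching MS/MS spectra against a
protein database, so the database bounds what can be found. For non-model
organisms, host–pathogen systems, or dynamic proteomes, reference proteomes
are incomplete or absent. *Proteomics informed by transcriptomics* (PIT)
replaces the reference with a database built from the same sample's
assembled transcripts: every transcript is translated in all six reading
frames, the open reading frames (ORFs) become the search database, and
identified peptides can then be projected back through the spliced
transcript-to-genome alignments to annotate the genome with direct protein
evidence.

`pitkit` implements the bespoke computational stages of this workflow — the
parts that sit between the off-the-shelf tools (assembler, search engine,
aligner, BLAST), whose *outputs* it consumes:

| Stage | Functions |
|---|---|
| Six-frame ORF database | `find_orfs()`, `build_orf_database()` |
| Target-decoy FDR | `generate_decoy_database()`, `peptide_level_scores()`, `compute_q_values()`, `filter_peptides()` |
| Protein inference | `map_peptides_to_proteins()`, `group_proteins()` |
| Genome annotation | `read_transcript_alignments()`, `project_interval()`, `project_peptide()`, `integrate_annotations()` (GFF3/SAM/TSV) |
| Search comparison | `tryptic_digest()`, `compare_peptides()`, `match_pags()`, `classify_unmatched()` |
| Synthetic ground truth | `sim_params()`, `simulate_scene()`, `simulate_psms()`, `simulate_homology()`, `run_pipeline()` |

## The statistics in brief

**Peptide-level FDR.** Each target protein gets a reversed decoy. PSMs are
collapsed to peptides (best score per modified sequence), ranked best
first, and at each rank the FDR is estimated as D/T from the cumulative
decoy and target counts; the q-value is the running minimum from the
bottom. Peptides with q ≤ 0.01 are retained by default.

**Protein ambiguity groups (PAGs).** Proteins sharing peptide evidence are
grouped: the protein with the most distinct peptides anchors the group
(ties broken alphabetically), equal peptide sets join as same-set members,
proper subsets as sub-members. Anchors with fewer than two distinct
peptides are discarded (the two-peptide rule).

**Comparison across searches.** Peptide lists from two searches are
compared on exact plain sequences; overlap is `100·shared/union`. Unique
identifications are attributed to database absence via an in-silico
tryptic digest of the opposing database. PAG lists are matched by homology
(BLAST e-value strictly below 1e-30), greedily, anchors first, one match
per PAG.

## Worked example

Everything runs offline on a simulated scene with known ground truth:

```r
library(pitkit)
run <- run_pipeline(sim_params(seed = 7, n_genes = 10))
run
#> PIT pipeline run (seed 7)
#>   transcripts: 10, ORFs: 121, PSMs: 11000
#>   peptides: 1315 scored, 619 retained at q <= threshold
#>   mapped: 619 (0 unmapped), PAGs: 109 (11 peptide(s) orphaned)
#>   peptide features: 608 (0 unprojectable)
#>   evidence conserved: TRUE
```

Ten simulated genes yield 121 six-frame ORFs; 11,000 scored PSMs collapse
to 1,315 peptides of which 619 survive the 1% peptide FDR; all of them map
into the ORF database, group into 109 ambiguity groups, and 608 peptide
occurrences project onto the genome — every one translating back to its
peptide sequence, splice- and strand-aware. `run$bundle` holds the GFF3
features, SAM records and the tabular summary.

The comparison arithmetic works directly on counts, e.g. for two searches
with 26,401 and 25,907 retained peptides of which 1,883 and 1,389 are
search-specific:

```r
peptide_overlap_from_counts(26401, 25907, 1883, 1389)
#> Peptide overlap: 24518 shared / 26401 vs 25907 (88% of union); unique 1883 + 1389
pag_match_report(1955, 813, unmatched_a = 247, unmatched_b = 158)
#> PAG matching: 1955 anchor-anchor + 813 anchor-submember = 2768 match(es); unmatched 247 + 158 (overlap 87%)
```

A thin command-line wrapper covers the same pipeline for shell use:

```sh
Rscript inst/exec/pit.R simulate --seed 42 --genes 50 --out scene/
Rscript inst/exec/pit.R orfs --transcripts scene/transcripts.fa --out scene/orfs.fa --index scene/orfs.tsv
Rscript inst/exec/pit.R fdr --psms scene/psms.tsv --threshold 0.01 --out scene/peptides.tsv
```

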