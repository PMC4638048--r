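---
title: "Methods: sample-specific search databases, peptide FDR, and genome projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sample-specific search databases, peptide FDR, and genome projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pitkit)
```

## Scope and model

`pitkit` covers the computational core of proteomics informed by
transcriptomics: building a protein search database from assembled
transcripts, controlling the peptide-level false discovery rate by
target-decoy competition, inferring proteins as ambiguity groups, placing
identified peptides on the genome through spliced alignments, and
comparing identification lists obtained with different databases. The
surrounding heavy machinery — read assembly, peptide-spectrum matching,
spliced alignment, BLAST — is deliberately out of scope; the package
consumes their standard outputs (FASTA, a PSM table or minimal mzIdentML,
GFF3/GTF exon features, tabular BLAST).

One convention holds throughout: internal coordinates are 0-based
half-open on every axis (transcript, protein, genome). Conversion to the
1-based inclusive coordinates of GFF3 and SAM happens only at
serialization. A single convention applied everywhere is the cheapest
defense against off-by-one drift across the three coordinate systems.

## Six-frame ORF finding

Frames +1/+2/+3 read the forward transcript at offsets 0/1/2; −1/−2/−3
read the reverse complement at the same offsets. Within a frame,
candidate ORFs are maximal stop-free codon runs. Two policies are
deliberately exposed rather than fixed, because de novo assembled
transcripts are frequently fragments:

* `require_start` (default `FALSE`): demanding an ATG would discard real
  protein C-terminal fragments whose start codon was not assembled. When
  set, a candidate is trimmed to its first ATG codon.
* `allow_partial` (default `TRUE`): runs open at a transcript end are
  kept and flagged `partial5`/`partial3`.

`mode` selects between at most one ORF per frame
(`per-frame-longest`, ties broken by the smaller forward-strand start,
for determinism) and every candidate above the length floor
(`all-above-min`). The floor defaults to `min_aa = 20`, about the
shortest ORF that can yield a confidently identifiable tryptic peptide.
Both modes are first-class: which one the original tooling used is not
derivable from its description, so neither is asserted as canonical and
the test suite exercises both against an independent enumeration oracle.

Ambiguity handling: codons containing `N` translate to `X` and do *not*
terminate a run (assembler ambiguity should not shatter an ORF), but
candidates that are more than 50% `X` are discarded as junk. Reported
coordinates are always forward-strand and exclude the stop codon, so
`nt_end − nt_start = 3 × length(aa)` is an invariant.

## Target-decoy FDR and q-values

Decoys are full sequence reversals with a `DECOY_` id prefix: reversal
preserves length and composition exactly, and the prefix makes decoy
detection string-exact. PSMs are collapsed to peptides keyed by sequence
plus modification string, keeping the best score; a peptide matching both
a target and a decoy protein counts as target. Ranked best-first (ties:
decoys before targets, the conservative order), the FDR estimate at rank
r is D(r)/max(T(r),1) — the "simple" convention; an estimator flag
switches to 2D/(T+D) for the competition convention. q-values are the
running minimum from the worst rank, capped at 1. Retention keeps targets
with q ≤ 0.01 by default, the conventional 1% peptide threshold.

Peptide identity is deliberately two different keys in different places:
sequence+modifications for FDR (two modified forms are separate
evidence), plain sequence for cross-search overlap (only exact sequence
matches count) and for the two-peptide rule (a flag switches the latter).

## Protein ambiguity grouping

Proteins are sorted by distinct peptide count, ties alphabetical, and
scanned once. Equality of peptide sets is checked against every existing
group's anchor before subset attachment, so same-set members (typically
isoforms) always land in their anchor's group; proper subsets attach to
the first group in creation order — the highest-evidence,
alphabetically-earliest anchor — which keeps the procedure deterministic
and permutation-invariant (shuffling the evidence never changes the
output; this is property-tested). Groups whose anchor has fewer than
`min_peptides = 2` distinct peptides are dropped, and peptides left
without any surviving group are reported as orphaned rather than silently
vanishing: `retained = covered + orphaned` is checked on every pipeline
run.

## Genome projection

A spliced alignment is an ordered set of exon blocks
`(t_start, t_end, g_start, g_end)`; blocks tile the transcript interval
`[0, L)` contiguously. On strand −, transcript coordinate 0 falls in the
block with the largest genome coordinate, and positions run against the
genome axis within each block. A transcript interval is projected by
intersecting it with each block and mapping affinely; junction-spanning
intervals yield multiple segments. Peptide offsets in an ORF convert to
transcript nucleotides as `nt_start + 3·offset` (reflected through the
ORF's own span for reverse frames), so total segment length is always
three times the peptide length.

Emission choices, made where the upstream description is silent and
declared rather than asserted as faithful:

* peptide features are emitted in nucleotide space (CDS-like), because
  genome browsers consume nucleotide-coordinate GFF3;
* multi-segment peptides use the GFF3 shared-ID multi-line convention
  (simplest form round-trippable by common browsers), with `Parent`
  links peptide → ORF → mRNA;
* the phase column is populated on CDS and peptide lines so frame-aware
  consumers can translate segments in reading order;
* SAM records encode segments as `M` runs and intron gaps as `N` runs,
  flag 16 and forward-genome-strand bases for reverse features;
* unprojectable items (an ORF extending past a truncated alignment) are
  tallied in the run report, never dropped.

The standing correctness criterion is the round trip: for every emitted
peptide feature, extracting its genome segments, reverse-complementing
when on −, concatenating and translating must reproduce the peptide
exactly. The test suite requires a 100% round-trip rate on a 50-gene
simulated scene, and the acceptance script recomputes that rate on a
fresh scene.

## Comparing searches

Peptide overlap is defined as shared/union of the plain-sequence sets —
the one definition consistent with both published overlap figures
recomputed from their printed totals and uniques, which the acceptance
arithmetic verifies. Search-specific peptides are attributed to database
absence by membership in the opposing database's fully tryptic digest
(cleave after K/R except before P; defaults: ≤2 missed cleavages, length
7–45 — exposed because the search engine's own missed-cleavage behavior
is not exactly reproducible).

PAG matching treats a BLAST e-value *strictly* below 1e-30 as evidence
that two identified sequences are the same protein. Matching is greedy
with each PAG usable once: pass 1 anchor↔anchor, pass 2
anchor↔(same-set/sub) member among the remainder, candidates ordered by
ascending e-value with ties broken on the normalized accession pair. The
published account reports totals per pass but no algorithm; the greedy
one-use rule is a declared choice, validated against an exhaustive
small-instance matcher and symmetric under label swap. Unmatched PAGs are
triaged by a first-hit-wins cascade (isoform of a matched group → no
transcript evidence → ORF failure → single-peptide in the other search →
extended ORF → no known homology); categories whose auxiliary input is
missing are disabled and recorded, never guessed.

## The synthetic scene: what it does and does not emulate

`simulate_scene()` builds the world the projection and FDR machinery
assume: two chromosomes, 50 spliced genes (1–4 exons of 60–240 nt,
introns 60–200 nt), half on the reverse strand, each transcript an exact
spliced extract of the genome. ORFs are *planted*, not rejection-sampled:
each transcript carries an in-frame stop immediately before an ATG, a
60–150 codon stop-free coding run, and a terminal stop, which guarantees
deterministically that the planted interval is a maximal stop-free run
recoverable by the finder. Ground-truth genome segments for planted
peptides are recorded by an independent per-base coordinate mapper, not
by the package's own interval projection, so the round-trip tests are a
genuine dual route.

`simulate_psms()` draws correct-match scores from Normal(25, 4) and
incorrect/decoy scores from Normal(12, 4), with 10% of the 10,000 target
PSMs incorrect and the decoy PSM count equal to the incorrect-target
count — the regime in which the decoy count calibrates the false-target
count and D/T is an unbiased FDR estimate. The Gaussian score model is a
documented stand-in for the statistical *structure* target-decoy FDR
assumes, not a claim about any search engine's score distribution.
Consequently, passing tests demonstrate coordinate correctness, FDR
calibration under the assumed model, and bookkeeping conservation — they
do not demonstrate robustness to chimeric transcripts, trans-splicing,
assembly errors within exons, or heavy-tailed score distributions, none
of which the generator produces.

Problem sizes used by the suite — 100 random transcripts up to 3 kb for
the six-frame oracle, 20 replicate simulations of 10,000 PSMs for the
calibration check, exhaustive 3×3 plus sampled 6×6 incidence matrices
for the grouping oracle, a 50-gene scene for the projection round trip —
were chosen as the smallest scales at which each property is
discriminating.

## Numerical and degenerate-input choices

* Score orientation is an explicit argument (`higher_is_better`, default
  `TRUE`), never sniffed from data.
* Zero peptides, empty FASTA files, and empty retained lists yield empty
  results, not errors; overlap of two empty sets is reported as 0%.
* Equal-length ORF candidates within a frame: smallest forward-strand
  start wins. Equal-score peptides: decoys rank ahead of targets.
  Anchor ties: alphabetical. Sub-member attachment ties: first group in
  creation order. Every tie-break is deterministic.
* I and L are distinct residues in peptide-to-protein mapping by default
  (`equate_il` flag available): the conservative choice given their
  identical mass.
* Thresholds are validated (`q` threshold in [0,1]; e-value threshold
  strict), and malformed input lines fail with their line number rather
  than being skipped.

## Known limitations

Full mzIdentML support is limited to reading spectrum/peptide/score/decoy
from SpectrumIdentificationResult items. BAM/CRAM are not written (SAM
only). Trans-spliced or fusion transcripts, alternative genetic codes,
and spectral-level processing are out of scope. The unmatched-PAG triage
depends on the auxiliary evidence supplied; with none it degrades to
distinguishing isoforms of matched groups from everything else.
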